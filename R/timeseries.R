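#' Regularly sampled one-dimensional signal
#'
#' Lightweight container for the per-subject signals handled by the
#' pipeline (gBOLD, CSF inflow, and derived series).  A `time_series`
#' carries its sampling interval so that lags can always be expressed in
#' seconds, and a flag recording whether it has been standardized.
#'
#' @param values numeric vector, length >= 3.
#' @param dt sampling interval in seconds (the fMRI repetition time for
#'   volume-derived signals), > 0.
#' @param standardized logical; `TRUE` only if `values` has mean 0 and
#'   population SD 1 (checked to 1e-9 relative tolerance).
#' @param t0 time of the first sample, seconds.  Derivative series use
#'   this to record their half-sample shift.
#' @return An object of class `time_series`.
#' @export
time_series <- function(values, dt, standardized = FALSE, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("time_series needs at least 3 samples")
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite values in time series")
  stop_if_not_scalar_pos(dt, "dt")
  if (isTRUE(standardized)) {
    m <- mean(values)
    s <- sqrt(mean((values - m)^2))
    if (abs(m) > 1e-9 || abs(s - 1) > 1e-9)
      stop("series marked standardized but mean/SD are not 0/1")
  }
  structure(list(values = values, dt = dt, standardized = isTRUE(standardized),
                 t0 = t0),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> n=%d dt=%gs%s\n", length(x$values), x$dt,
              if (x$standardized) " (z-scored)" else ""))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

as_time_series <- function(x, dt) {
  if (inherits(x, "time_series")) x else time_series(x, dt)
}

#' Remove polynomial trends from a series
#'
#' Least-squares removal of a polynomial trend up to `degree` (degree 2,
#' the default, removes constant + linear + quadratic components, the
#' conventional fMRI drift model).  The residual is orthogonal to the
#' polynomial basis.
#'
#' @param ts a [time_series()].
#' @param degree 1 or 2.
#' @return detrended `time_series`.
#' @export
detrend <- function(ts, degree = 2) {
  stopifnot(inherits(ts, "time_series"))
  if (!degree %in% c(1, 2)) stop("`degree` must be 1 or 2")
  n <- length(ts$values)
  if (n <= degree + 1) stop("series too short for requested detrending degree")
  res <- detrend_matrix(matrix(ts$values, ncol = 1L), degree)[, 1L]
  time_series(res, ts$dt, t0 = ts$t0)
}

# Column-wise polynomial detrending of a time-by-channel matrix.
detrend_matrix <- function(x, degree = 2) {
  n <- nrow(x)
  tt <- seq_len(n) / n  # scaled time, conditioning
  basis <- stats::poly(tt, degree = degree, raw = FALSE)
  X <- cbind(1, basis)
  qr.resid(qr(X), x)
}

#' Standardize a series to zero mean and unit variance
#'
#' Uses the population standard deviation (divisor N) so the lagged
#' inner products downstream are exactly Pearson correlations.
#'
#' @param ts a [time_series()].
#' @return standardized `time_series`.
#' @export
zscore <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  v <- ts$values
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s <= 0 || !is.finite(s)) stop("cannot z-score a constant series")
  time_series((v - m) / s, ts$dt, standardized = TRUE, t0 = ts$t0)
}

#' Negative first-order temporal derivative
#'
#' Forward difference: `out[i] = -(x[i+1] - x[i]) / dt`, length `N - 1`.
#' The result lives on the midpoint grid, i.e. its timestamps are
#' shifted by half a sample; this is recorded in the `t0` field.  The
#' negative derivative of the gBOLD signal is the model-motivated
#' partner of the CSF inflow signal (CSF inflow tracks decreases in
#' cerebral blood volume).
#'
#' @param ts a [time_series()] of length >= 2... (>= 4 so the result is
#'   a valid series).
#' @return `time_series` of length `N - 1`, `t0` advanced by `dt / 2`.
#' @export
negative_derivative <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  n <- length(ts$values)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  v <- -diff(ts$values) / ts$dt
  time_series(v, ts$dt, t0 = ts$t0 + ts$dt / 2)
}
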