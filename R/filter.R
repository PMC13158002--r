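# Butterworth band-pass design and zero-phase filtering.
#
# The preprocessing applies a 4th-order Butterworth band-pass
# (0.01-0.1 Hz) forward and backward (zero phase).  Zero phase matters:
# the analysis quantifies lags between signals, so the filter must not
# introduce a group delay.  No IIR design/filtering routine is
# available among the package's allowed dependencies, so the standard
# design path (analog prototype -> band transform -> bilinear
# transform) and a filtfilt with odd-reflection padding and
# steady-state initial conditions are implemented here.

#' Band-pass filter specification
#'
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < ` Nyquist of the filtered series.
#' @param order Butterworth prototype order (default 4; the band
#'   transform doubles the pole count).
#' @param zero_phase apply forward-backward (default TRUE).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.01, high_hz = 0.1, order = 4, zero_phase = TRUE) {
  stop_if_not_scalar_pos(low_hz, "low_hz")
  stop_if_not_scalar_pos(high_hz, "high_hz")
  if (low_hz >= high_hz) stop("low_hz must be < high_hz")
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# Butterworth band-pass coefficients (b, a) for sampling rate fs.
butter_bandpass <- function(low_hz, high_hz, fs, order = 4) {
  nyq <- fs / 2
  if (high_hz >= nyq) stop("high edge at or above Nyquist frequency")
  fs2 <- 2 * fs
  # pre-warped analog edges
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each prototype pole splits into two
  half <- bw * p_lp / 2
  delta <- sqrt(half^2 - w0^2)
  p_bp <- c(half + delta, half - delta)
  # analog gain B^order with `order` zeros at s = 0
  # bilinear transform
  zd <- rep(-1 + 0i, order)               # zeros at z = -1 (from s = Inf)
  zd <- c(rep(1 + 0i, order), zd)         # zeros at z = +1 (from s = 0)
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  gain <- Re(bw^order * fs2^order / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Direct-form II transposed IIR filter applied down the rows of a
# matrix (time x channels); zi is the initial state (m x ncol).
iir_filter_matrix <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  nt <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nt, nc)
  z <- if (is.null(zi)) matrix(0, m, nc) else zi
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (m > 1L)
      z[seq_len(m - 1L), ] <- b[2:m] * rep(xt, each = m - 1L) +
        z[2:m, , drop = FALSE] - a[2:m] * rep(yt, each = m - 1L)
    z[m, ] <- b[m + 1L] * xt - a[m + 1L] * yt
    y[t, ] <- yt
  }
  y
}

# Steady-state initial filter state for a unit step input.
iir_step_state <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  # companion matrix of a (transposed), as in the textbook state-space
  A <- matrix(0, m, m)
  A[, 1] <- -a[2:(m + 1L)]
  if (m > 1L) A[cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)] <- 1
  B <- b[2:(m + 1L)] - a[2:(m + 1L)] * b[1]
  solve(diag(m) - A, B)
}

# Zero-phase filtering down matrix rows with odd-reflection padding.
filtfilt_matrix <- function(b, a, x) {
  nt <- nrow(x)
  padlen <- 3L * max(length(a), length(b))
  if (nt <= padlen)
    stop(sprintf("series too short to band-pass filter (need > %d samples)", padlen))
  zi <- iir_step_state(b, a)
  ext <- rbind(
    2 * x[rep(1L, padlen), , drop = FALSE] - x[(padlen + 1L):2L, , drop = FALSE],
    x,
    2 * x[rep(nt, padlen), , drop = FALSE] - x[(nt - 1L):(nt - padlen), , drop = FALSE]
  )
  y <- iir_filter_matrix(b, a, ext, zi = zi %o% ext[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- iir_filter_matrix(b, a, y, zi = zi %o% y[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(padlen + 1L):(padlen + nt), , drop = FALSE]
}

# Band-pass a time-by-channel matrix sampled at interval dt.
bandpass_matrix <- function(x, dt, spec = filter_spec()) {
  fs <- 1 / dt
  if (spec$high_hz >= fs / 2)
    stop("filter passband edge at or above the Nyquist frequency")
  ba <- butter_bandpass(spec$low_hz, spec$high_hz, fs, spec$order)
  if (spec$zero_phase) {
    filtfilt_matrix(ba$b, ba$a, x)
  } else {
    iir_filter_matrix(ba$b, ba$a, x)
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters the series with a Butterworth band-pass applied
#' forward-backward, so the magnitude response is squared and the phase
#' response is identically zero.  Defaults reproduce the 0.01-0.1 Hz
#' band conventionally used to isolate low-frequency BOLD/CSF
#' fluctuations.
#'
#' @param ts a [time_series()].
#' @param spec a [filter_spec()].
#' @return filtered `time_series`.
#' @export
bandpass <- function(ts, spec = filter_spec()) {
  stopifnot(inherits(ts, "time_series"), inherits(spec, "filter_spec"))
  y <- bandpass_matrix(matrix(ts$values, ncol = 1L), ts$dt, spec)[, 1L]
  time_series(y, ts$dt, t0 = ts$t0)
}
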