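# Lagged gBOLD-CSF cross-correlation, the +4 s coupling-strength
# metric, derivative coupling, and the subject-shuffling permutation
# null.
#
# Lag sign convention, fixed throughout the package: the curve value
# at lag k (seconds) is the Pearson correlation of the pairs
# (g[t + k/dt], c[t]).  NEGATIVE lag therefore means gBOLD leads CSF.
# The physiological pattern is a positive correlation peak at negative
# lag (a gBOLD peak precedes the CSF peak) and a negative peak at
# positive lag, whose value at +4 s is the headline per-subject
# coupling strength.

#' Coupling analysis configuration
#'
#' @param max_lag_s half-width of the lag window in seconds
#'   (default 10).
#' @param metric_lag_s fixed lag at which coupling strength is read
#'   (default +4 s).
#' @param metric_mode `"fixed-lag"` (default; value at exactly
#'   `+metric_lag_s`) or `"searched-minimum"` (minimum over positive
#'   lags, for sensitivity analysis).
#' @return a `coupling_config` list.
#' @export
coupling_config <- function(max_lag_s = 10, metric_lag_s = 4,
                            metric_mode = c("fixed-lag", "searched-minimum")) {
  metric_mode <- match.arg(metric_mode)
  stop_if_not_scalar_pos(max_lag_s, "max_lag_s")
  stop_if_not_scalar_pos(metric_lag_s, "metric_lag_s")
  if (metric_lag_s > max_lag_s) stop("metric_lag_s must be <= max_lag_s")
  structure(list(max_lag_s = max_lag_s, metric_lag_s = metric_lag_s,
                 metric_mode = metric_mode),
            class = "coupling_config")
}

new_coupling_curve <- function(lags_s, r, n_pairs, dt) {
  structure(list(lags_s = lags_s, r = r, n_pairs = n_pairs, dt = dt),
            class = "coupling_curve")
}

#' @export
print.coupling_curve <- function(x, ...) {
  cat(sprintf("<coupling_curve> lags %g..%g s (step %g)\n",
              min(x$lags_s), max(x$lags_s), x$dt))
  print(stats::setNames(round(x$r, 4), x$lags_s))
  invisible(x)
}

align_pair <- function(g, c) {
  stopifnot(inherits(g, "time_series"), inherits(c, "time_series"))
  if (abs(g$dt - c$dt) > 1e-9) stop("series have different sampling intervals")
  ng <- length(g$values); nc <- length(c$values)
  if (abs(ng - nc) > 1L)
    stop("series lengths differ by more than one sample")
  n <- min(ng, nc)
  list(g = g$values[seq_len(n)], c = c$values[seq_len(n)], n = n, dt = g$dt)
}

#' Lagged cross-correlation curve
#'
#' For each lag `k` on the grid (multiples of the sampling interval,
#' spanning `±max_lag_s`), computes the Pearson correlation of the
#' overlapping pairs `(g[t + k], c[t])`, with means and SDs recomputed
#' on each lag's own overlap segment so that `|r| <= 1` holds exactly
#' at every lag.
#'
#' @param g,c [time_series()] objects with equal `dt`; lengths may
#'   differ by one sample (the common prefix is used).
#' @param cfg a [coupling_config()].
#' @return a `coupling_curve` with fields `lags_s`, `r`, `n_pairs`.
#' @export
cross_correlation <- function(g, c, cfg = coupling_config()) {
  a <- align_pair(g, c)
  K <- round(cfg$max_lag_s / a$dt)
  if (a$n <= 2L * K)
    stop(sprintf("series too short (%d samples) for a ±%g s lag window",
                 a$n, cfg$max_lag_s))
  ks <- (-K):K
  r <- n_pairs <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k >= 0) {
      gs <- a$g[(1 + k):a$n]; cs <- a$c[1:(a$n - k)]
    } else {
      gs <- a$g[1:(a$n + k)]; cs <- a$c[(1 - k):a$n]
    }
    if (stats::sd(gs) == 0 || stats::sd(cs) == 0)
      stop(sprintf("zero variance in overlap segment at lag %g s", k * a$dt))
    r[i] <- stats::cor(gs, cs)
    n_pairs[i] <- length(gs)
  }
  new_coupling_curve(ks * a$dt, r, n_pairs, a$dt)
}

#' Coupling strength from a curve
#'
#' Fixed-lag mode (default) returns the curve value at exactly
#' `+metric_lag_s` — the negative-peak correlation at approximately
#' +4 s that serves as the per-subject glymphatic proxy.  Searched
#' mode returns the minimum over strictly positive lags.  If the
#' metric lag is not on the lag grid it is rounded to the nearest grid
#' point with a warning.
#'
#' @param curve a `coupling_curve`.
#' @param cfg a [coupling_config()].
#' @return scalar correlation, with attribute `metric_mode` (and
#'   `lag_s`, the lag actually used).
#' @export
coupling_strength <- function(curve, cfg = coupling_config()) {
  stopifnot(inherits(curve, "coupling_curve"))
  if (cfg$metric_mode == "fixed-lag") {
    i <- which(abs(curve$lags_s - cfg$metric_lag_s) < 1e-9)
    if (length(i) == 0L) {
      i <- which.min(abs(curve$lags_s - cfg$metric_lag_s))
      if (abs(curve$lags_s[i] - cfg$metric_lag_s) > curve$dt / 2 + 1e-9)
        stop(sprintf("metric lag %g s absent from the lag grid", cfg$metric_lag_s))
      warning(sprintf("metric lag %g s not on the lag grid; using %g s",
                      cfg$metric_lag_s, curve$lags_s[i]))
    }
    out <- curve$r[i]
    attr(out, "lag_s") <- curve$lags_s[i]
  } else {
    pos <- curve$lags_s > 0
    if (!any(pos)) stop("no positive lags on the curve")
    i <- which(pos)[which.min(curve$r[pos])]
    out <- curve$r[i]
    attr(out, "lag_s") <- curve$lags_s[i]
  }
  attr(out, "metric_mode") <- cfg$metric_mode
  out
}

# Index of the extremum under the tie rule: smallest |lag| first,
# then negative before positive.
peak_index <- function(lags, vals, decreasing) {
  ord <- order(abs(lags), lags)
  cand <- if (decreasing) which(vals == max(vals)) else which(vals == min(vals))
  ord[ord %in% cand][1L]
}

#' Positive and negative peaks of a coupling curve
#'
#' Argmax and argmin over the lag grid.  Exact ties are broken toward
#' the smallest absolute lag, then toward the negative lag.
#'
#' @param curve a `coupling_curve`.
#' @return list with `pos_peak` and `neg_peak`, each `(lag_s, r)`.
#' @export
find_peaks <- function(curve) {
  stopifnot(inherits(curve, "coupling_curve"))
  if (length(curve$r) == 0L) stop("empty curve")
  ip <- peak_index(curve$lags_s, curve$r, decreasing = TRUE)
  im <- peak_index(curve$lags_s, curve$r, decreasing = FALSE)
  list(pos_peak = list(lag_s = curve$lags_s[ip], r = curve$r[ip]),
       neg_peak = list(lag_s = curve$lags_s[im], r = curve$r[im]))
}

#' Cross-correlation between -d(gBOLD)/dt and the CSF signal
#'
#' The model behind the coupling metric holds that CSF inflow tracks
#' decreases in cerebral blood volume, i.e. the negative temporal
#' derivative of the global signal.  This computes the lagged
#' cross-correlation between that derivative and the CSF series.
#'
#' The derivative estimator used here is the central difference
#' `-(g[i+1] - g[i-1]) / (2 dt)`, which is phase-neutral: it lives on
#' the same time grid as `g` itself, so the derivative curve's lag
#' axis is directly comparable with the raw gBOLD-CSF curve.  (The
#' forward difference of [negative_derivative()] carries a half-sample
#' time shift, which at TR = 2 s would displace the derivative peak by
#' a full second.)  The partner series is trimmed by one sample at
#' each end to align.
#'
#' @param g,c [time_series()] objects (raw gBOLD and CSF).
#' @param cfg a [coupling_config()].
#' @return a `coupling_curve`.
#' @export
derivative_coupling <- function(g, c, cfg = coupling_config()) {
  stopifnot(inherits(g, "time_series"), inherits(c, "time_series"))
  n <- length(g$values)
  if (n < 3L) stop("need at least 3 samples for the central difference")
  nd <- time_series(-(g$values[3:n] - g$values[1:(n - 2)]) / (2 * g$dt),
                    g$dt, t0 = g$t0 + g$dt)
  nc <- length(c$values)
  hi <- min(n - 1L, nc)
  if (hi < 4L) stop("CSF series too short for derivative coupling")
  ct <- time_series(c$values[2:hi], c$dt, t0 = c$t0 + c$dt)
  cross_correlation(nd, ct, cfg)
}

#' Pointwise mean of coupling curves
#'
#' @param curves list of `coupling_curve` objects on identical lag
#'   grids.
#' @return a `coupling_curve` whose `r` is the arithmetic mean and
#'   whose `n_pairs` is the per-lag mean of the inputs'.
#' @export
group_mean_curve <- function(curves) {
  if (length(curves) == 0L) stop("no curves")
  lags <- curves[[1L]]$lags_s
  for (cu in curves) {
    stopifnot(inherits(cu, "coupling_curve"))
    if (!isTRUE(all.equal(cu$lags_s, lags)))
      stop("coupling curves have mismatching lag grids")
  }
  rmat <- vapply(curves, function(cu) cu$r, numeric(length(lags)))
  npmat <- vapply(curves, function(cu) cu$n_pairs, numeric(length(lags)))
  new_coupling_curve(lags, rowMeans(rmat), rowMeans(npmat), curves[[1L]]$dt)
}

# Pearson correlation at a single fixed lag for every (g_i, c_j) pair.
pairwise_lag_correlation <- function(gmat, cmat, k) {
  n <- nrow(gmat)
  if (k >= 0) {
    gs <- gmat[(1 + k):n, , drop = FALSE]; cs <- cmat[1:(n - k), , drop = FALSE]
  } else {
    gs <- gmat[1:(n + k), , drop = FALSE]; cs <- cmat[(1 - k):n, , drop = FALSE]
  }
  stats::cor(gs, cs)
}

random_derangement <- function(n) {
  if (n < 3L) stop("derangements need n >= 3")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Subject-shuffling permutation null for the coupling statistic
#'
#' The observed statistic is the mean, over subjects, of the
#' fixed-lag (+4 s by default) gBOLD-CSF correlation of the true
#' pairings.  Each null iteration re-pairs gBOLD and CSF signals
#' across subjects by a random derangement (no subject keeps its own
#' CSF signal) and computes the same mean statistic.  The two-sided p
#' is `(#\{|null| >= |observed|\} + 1) / (n_iter + 1)`.
#'
#' @param gbold_by_subject,csf_by_subject lists of [time_series()],
#'   one per subject (>= 3 subjects); series are truncated to the
#'   common minimum length.
#' @param cfg a [coupling_config()]; only `metric_lag_s` is used.
#' @param n_iter number of iterations (default 10000).
#' @param seed RNG seed (applied locally).
#' @param derangement if `FALSE`, plain random permutations are used
#'   instead (self-pairings allowed).
#' @return a `null_distribution` list: `n_iter`, `values`, `seed`,
#'   `observed`, `p_two_sided`.
#' @export
permutation_null <- function(gbold_by_subject, csf_by_subject,
                             cfg = coupling_config(), n_iter = 10000,
                             seed = 1, derangement = TRUE) {
  ns <- length(gbold_by_subject)
  if (ns < 3L) stop("permutation null needs at least 3 subjects")
  if (length(csf_by_subject) != ns) stop("subject lists differ in length")
  dt <- gbold_by_subject[[1L]]$dt
  nmin <- min(vapply(gbold_by_subject, length, 1L),
              vapply(csf_by_subject, length, 1L))
  k <- round(cfg$metric_lag_s / dt)
  if (nmin <= k + 2L) stop("series too short for the metric lag")
  gmat <- vapply(gbold_by_subject, function(s) s$values[seq_len(nmin)],
                 numeric(nmin))
  cmat <- vapply(csf_by_subject, function(s) s$values[seq_len(nmin)],
                 numeric(nmin))
  R <- pairwise_lag_correlation(gmat, cmat, k)
  observed <- mean(diag(R))
  values <- with_local_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      p <- if (derangement) random_derangement(ns) else sample.int(ns)
      mean(R[cbind(seq_len(ns), p)])
    }, numeric(1))
  })
  p <- (sum(abs(values) >= abs(observed)) + 1) / (n_iter + 1)
  structure(list(n_iter = n_iter, values = values, seed = seed,
                 observed = observed, p_two_sided = p),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> n_iter=%d observed=%.4f p=%.4g\n",
              x$n_iter, x$observed, x$p_two_sided))
  invisible(x)
}
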