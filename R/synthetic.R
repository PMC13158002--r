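# Seeded synthetic cohorts with ground truth.
#
# The generator's signal model: gBOLD is a unit-variance narrowband
# Gaussian process (white noise band-limited to f0 +/- bandwidth/2 in
# the frequency domain), and the CSF inflow signal is the negative
# temporal derivative of gBOLD, delayed, plus white noise whose SD is
# calibrated so the expected lagged correlation at the metric lag hits
# a per-subject target.  With the defaults (f0 = 1/24 Hz, delay 2 s)
# the analytic negative peak of the gBOLD-CSF curve falls at
# 1/(4 f0) - delay = +4 s and the derivative-coupling peak at
# -delay = -2 s, the lag structure the analysis is designed to
# recover.  The derivative and the delay are applied spectrally
# (multiplication by i*2*pi*f and a linear-phase factor), so the model
# holds exactly on the sampled grid with no estimator phase shift.
# The narrow bandwidth (0.02 Hz) keeps the autocorrelation envelope
# nearly flat over +/-10 s so the sampled peak lags match the analytic
# values.

#' Synthetic cohort configuration
#'
#' Defaults state the emulated study: group sizes 29 + 37, 240
#' volumes at TR 2 s, group mean couplings -0.240 (BQD) and -0.111
#' (HC) with SDs 0.200 / 0.225 at the +4 s lag, a duration covariate
#' correlated ~0.43 with coupling, clinical-score moments matched to
#' the cohort table, and ~7% of subjects violating the 1.5 mm / 1.5
#' degree motion limits.
#'
#' @param n_bqd,n_hc group sizes.
#' @param n_volumes volumes per scan (pre-discard).
#' @param tr repetition time, seconds.
#' @param f0 centre frequency of the gBOLD band, Hz.
#' @param bandwidth full width of the band, Hz.
#' @param delay_s CSF lag behind -d(gBOLD)/dt, seconds.
#' @param target_coupling length-2 named numeric `c(bqd=, hc=)`:
#'   expected r at the metric lag per group.
#' @param coupling_sd per-group SD of the subject-level couplings.
#' @param duration_r correlation between BQD duration and coupling.
#' @param grid_dim,voxel_size_mm spatial grid for rendered volumes.
#' @param voxel_noise_sd SD of independent voxel noise (signal has
#'   unit variance).
#' @param motion_violation_fraction fraction of subjects given
#'   super-threshold motion traces.
#' @param seed master RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_bqd = 29, n_hc = 37, n_volumes = 240, tr = 2,
                             f0 = 1 / 24, bandwidth = 0.02, delay_s = 2,
                             target_coupling = c(bqd = -0.240, hc = -0.111),
                             coupling_sd = c(bqd = 0.200, hc = 0.225),
                             duration_r = 0.4313,
                             grid_dim = c(16, 16, 8),
                             voxel_size_mm = c(3.5, 3.5, 3.5),
                             voxel_noise_sd = 1,
                             motion_violation_fraction = 0.07,
                             seed = 1) {
  if (n_bqd < 2 || n_hc < 2) stop("group sizes must be >= 2")
  stop_if_not_scalar_pos(tr, "tr")
  if (f0 - bandwidth / 2 <= 0) stop("band extends to or below 0 Hz")
  if (f0 + bandwidth / 2 >= 1 / (2 * tr)) stop("band extends to or above Nyquist")
  if (any(abs(target_coupling) >= 1)) stop("|target_coupling| must be < 1")
  if (length(grid_dim) != 3L || any(grid_dim[1:2] < 6) || grid_dim[3] < 3)
    stop("grid_dim must be at least 6 x 6 x 3")
  structure(list(n_bqd = n_bqd, n_hc = n_hc, n_volumes = n_volumes, tr = tr,
                 f0 = f0, bandwidth = bandwidth, delay_s = delay_s,
                 target_coupling = target_coupling, coupling_sd = coupling_sd,
                 duration_r = duration_r, grid_dim = as.integer(grid_dim),
                 voxel_size_mm = voxel_size_mm,
                 voxel_noise_sd = voxel_noise_sd,
                 motion_violation_fraction = motion_violation_fraction,
                 seed = seed),
            class = "synthetic_config")
}

# Band-limited Gaussian process and its exact negative derivative,
# delayed by `m` samples.  Returns N samples of each, aligned so that
# csf_component[i] = -g'(t_i - m*tr).  Consumes the current RNG.
narrowband_pair_raw <- function(n, tr, f0, bandwidth, m) {
  L <- n + m
  x <- stats::rnorm(L)
  X <- stats::fft(x)
  j <- seq_len(L) - 1L
  f <- ifelse(j <= L / 2, j, j - L) / (L * tr)
  keep <- abs(abs(f) - f0) <= bandwidth / 2
  X[!keep] <- 0
  G <- Re(stats::fft(X, inverse = TRUE)) / L
  D <- Re(stats::fft(X * (2i * pi * f), inverse = TRUE)) / L
  # g[i] = G[m + i]; csf component = -g'(t_i - m*tr) = -D[i]
  list(g = G[(m + 1L):(m + n)], neg_dg_delayed = -D[seq_len(n)])
}

pop_z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))

delay_samples <- function(config) {
  mexact <- config$delay_s / config$tr
  m <- round(mexact)
  if (abs(mexact - m) > 1e-9)
    warning(sprintf("delay %g s is not a multiple of TR %g s; rounded to %d samples",
                    config$delay_s, config$tr, m))
  max(m, 0L)
}

# cache of noise-free metric-lag couplings keyed by generator shape
.ideal_cache <- new.env(parent = emptyenv())

#' Noise-free coupling of the generator at the metric lag
#'
#' Estimates, by long-series simulation under a fixed internal seed,
#' the expected correlation at `metric_lag_s` between gBOLD and the
#' noise-free CSF component.  This is the ceiling that calibrated
#' noise attenuates; with the defaults it is ~ -0.97.
#'
#' @param config a [synthetic_config()].
#' @param metric_lag_s metric lag, seconds (default 4).
#' @return scalar correlation (negative with the defaults).
#' @export
ideal_coupling <- function(config, metric_lag_s = 4) {
  key <- paste(config$tr, config$f0, config$bandwidth, config$delay_s,
               metric_lag_s, sep = "|")
  if (!is.null(.ideal_cache[[key]])) return(.ideal_cache[[key]])
  m <- delay_samples(config)
  k <- round(metric_lag_s / config$tr)
  val <- with_local_seed(987654321L, {
    rs <- vapply(1:6, function(i) {
      p <- narrowband_pair_raw(8192L, config$tr, config$f0, config$bandwidth, m)
      n <- length(p$g)
      stats::cor(p$g[(1 + k):n], p$neg_dg_delayed[1:(n - k)])
    }, numeric(1))
    mean(rs)
  })
  .ideal_cache[[key]] <- val
  val
}

#' Noise SD achieving a target expected coupling
#'
#' The CSF signal is `s * d + sigma * eps` with `d` the unit-variance
#' noise-free component; the expected metric-lag correlation is then
#' `r_ideal / sqrt(1 + sigma^2)`.  This closed form (solved for
#' `sigma`) initializes an optional bisection against simulated
#' estimates under a fixed inner seed (tolerance `tol`).
#'
#' @param config a [synthetic_config()].
#' @param target_r target expected correlation; `|target_r|` must lie
#'   in `[0.01, |r_ideal|]`.
#' @param refine run the simulation bisection (default `FALSE`: the
#'   closed form is already exact in expectation).
#' @param tol bisection tolerance on the achieved correlation.
#' @return noise SD (>= 0).
#' @export
calibrate_noise <- function(config, target_r, refine = FALSE, tol = 0.01) {
  r_ideal <- ideal_coupling(config)
  if (abs(target_r) < 0.01)
    stop("|target_r| must be at least 0.01 (noise SD would diverge)")
  if (abs(target_r) > abs(r_ideal))
    stop(sprintf("unattainable target %g: noise-free coupling is %g",
                 target_r, r_ideal))
  sigma <- sqrt(max((r_ideal / target_r)^2 - 1, 0))
  if (!refine) return(sigma)
  m <- delay_samples(config)
  k <- round(config$tr * 0 + 4 / config$tr)
  simulate_r <- function(s) with_local_seed(192837465L, {
    rs <- vapply(1:8, function(i) {
      p <- narrowband_pair_raw(4096L, config$tr, config$f0, config$bandwidth, m)
      cvals <- sign(target_r / r_ideal) * pop_z(p$neg_dg_delayed) +
        s * stats::rnorm(length(p$g))
      n <- length(p$g)
      stats::cor(p$g[(1 + k):n], cvals[1:(n - k)])
    }, numeric(1))
    mean(rs)
  })
  lo <- 0; hi <- max(2 * sigma, 1)
  while (abs(simulate_r(hi)) > abs(target_r)) hi <- hi * 2
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    r <- simulate_r(mid)
    if (abs(r - target_r) <= tol) return(mid)
    if (abs(r) > abs(target_r)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' One subject's gBOLD and CSF signal pair
#'
#' @param config a [synthetic_config()].
#' @param subject_coupling target expected correlation at the +4 s
#'   lag.  Magnitudes below 0.01 produce a pure-noise CSF signal
#'   (zero coupling).
#' @param seed RNG seed for this subject.
#' @return list of two z-scored [time_series()]: `gbold`, `csf`; the
#'   applied noise SD is attached as attribute `noise_sd`.
#' @export
generate_signal_pair <- function(config, subject_coupling, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  m <- delay_samples(config)
  n <- config$n_volumes
  r_ideal <- ideal_coupling(config)
  with_local_seed(seed, {
    p <- narrowband_pair_raw(n, config$tr, config$f0, config$bandwidth, m)
    g <- pop_z(p$g)
    if (abs(subject_coupling) < 0.01) {
      cvals <- stats::rnorm(n)
      sigma <- Inf
    } else {
      sigma <- calibrate_noise(config, subject_coupling)
      s <- if (sign(subject_coupling) == sign(r_ideal)) 1 else -1
      cvals <- s * pop_z(p$neg_dg_delayed) + sigma * stats::rnorm(n)
    }
    out <- list(gbold = time_series(g, config$tr, standardized = TRUE),
                csf = zscore(time_series(cvals, config$tr)))
    attr(out, "noise_sd") <- sigma
    out
  })
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# A smooth motion trace; violators exceed the translation limit.
generate_motion_trace <- function(n_volumes, violate) {
  smooth6 <- function(target_max) {
    w <- apply(matrix(stats::rnorm(n_volumes * 3), ncol = 3), 2, cumsum)
    w <- sweep(w, 2, w[1, ])
    sweep(w, 2, apply(abs(w), 2, max) / target_max, "/")
  }
  tr_max <- stats::runif(3, 0.05, if (violate) 0.6 else 0.9)
  rot_max <- stats::runif(3, 0.02, if (violate) 0.3 else 0.6)
  trans <- smooth6(1)
  rot <- smooth6(1)
  trans <- sweep(trans, 2, tr_max, "*")
  rot <- sweep(rot, 2, rot_max, "*")
  if (violate) {
    ax <- sample.int(3, 1)
    trans[, ax] <- trans[, ax] / max(abs(trans[, ax])) * stats::runif(1, 1.6, 2.5)
  }
  motion_trace(trans, rot)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws per-subject ideal couplings from the group distributions
#' (normal, truncated to (-0.95, 0.95); draws with magnitude under
#' 0.01 yield uncoupled, pure-noise CSF signals), clinical scores
#' from truncated normals matched to the cohort-table moments, a BQD
#' duration linearly tied to the subject coupling to achieve the
#' configured correlation in expectation, and the signal pairs
#' themselves.  A configured fraction of subjects receives motion
#' traces violating the 1.5 mm / 1.5 degree limits.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (subject data.frame), `signals` (list
#'   of `generate_signal_pair()` outputs), `motion` (list of
#'   [motion_trace()]), `ground_truth` (data.frame), `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_bqd + config$n_hc
  group <- rep(c("BQD", "HC"), c(config$n_bqd, config$n_hc))
  ids <- sprintf("sub-%03d", seq_len(n))
  meta <- with_local_seed(config$seed, {
    tc <- config$target_coupling
    csd <- config$coupling_sd
    ideal <- numeric(n)
    ideal[group == "BQD"] <- rtrunc_norm(config$n_bqd, tc[["bqd"]], csd[["bqd"]],
                                         -0.95, 0.95)
    ideal[group == "HC"] <- rtrunc_norm(config$n_hc, tc[["hc"]], csd[["hc"]],
                                        -0.95, 0.95)
    # draws with |r| < 0.01 become uncoupled subjects (pure-noise CSF
    # in generate_signal_pair) rather than clamping to the 0.01 floor
    rho <- config$duration_r
    zc <- (ideal[group == "BQD"] - tc[["bqd"]]) / csd[["bqd"]]
    dur_noise <- stats::rnorm(config$n_bqd)
    duration <- pmax(15.3 + 7.4 * (rho * zc + sqrt(1 - rho^2) * dur_noise), 0.5)
    sex <- ifelse(group == "BQD",
                  ifelse(stats::runif(n) < 13 / 29, "M", "F"),
                  ifelse(stats::runif(n) < 5 / 37, "M", "F"))
    age <- round(ifelse(group == "BQD",
                        rtrunc_norm(n, 42, 8, 18, 60),
                        rtrunc_norm(n, 37, 11, 18, 60)))
    education <- round(ifelse(group == "BQD",
                              rtrunc_norm(n, 10.5, 2.5, 1, 22),
                              rtrunc_norm(n, 14, 3.5, 1, 22)))
    hama <- pmin(pmax(round(stats::rnorm(n, 2.3, 1.8)), 0), 7)
    hamd <- pmin(pmax(round(stats::rnorm(n, 3.2, 2.2)), 0), 7)
    bqds <- rtrunc_norm(config$n_bqd, 8.8, 2.7, 4 + 1e-9, Inf)
    dose <- rtrunc_norm(config$n_bqd, 6.1, 7.2, 0.5, Inf)
    violate <- stats::runif(n) < config$motion_violation_fraction
    list(ideal = ideal, duration = duration, sex = sex, age = age,
         education = education, hama = hama, hamd = hamd, bqds = bqds,
         dose = dose, violate = violate)
  })
  signals <- vector("list", n)
  motion <- vector("list", n)
  noise_sd <- numeric(n)
  for (i in seq_len(n)) {
    signals[[i]] <- generate_signal_pair(config, meta$ideal[i],
                                         seed = derive_seed(config$seed, i))
    noise_sd[i] <- attr(signals[[i]], "noise_sd")
    motion[[i]] <- with_local_seed(derive_seed(config$seed, n + i),
                                   generate_motion_trace(config$n_volumes,
                                                         meta$violate[i]))
  }
  is_bqd <- group == "BQD"
  records <- data.frame(
    id = ids, group = group, sex = meta$sex, age = meta$age,
    education = meta$education,
    bqds = NA_real_, duration = NA_real_, daily_dose = NA_real_,
    hama14 = meta$hama, hamd24 = meta$hamd,
    coupling = NA_real_, qc_pass = NA, stringsAsFactors = FALSE)
  records$bqds[is_bqd] <- round(meta$bqds, 1)
  records$duration[is_bqd] <- round(meta$duration, 1)
  records$daily_dose[is_bqd] <- round(meta$dose, 1)
  ground_truth <- data.frame(
    id = ids, group = group, ideal_coupling = meta$ideal,
    noise_sd = noise_sd, motion_violation = meta$violate,
    stringsAsFactors = FALSE)
  list(records = records, signals = signals, motion = motion,
       ground_truth = ground_truth, config = config)
}

# Disjoint grey-matter and bottom-slice CSF masks on the config grid.
default_masks <- function(config, csf_in_bottom_slice = TRUE) {
  d <- config$grid_dim
  gm <- array(FALSE, dim = d)
  xs <- max(2L, floor(d[1] * 0.25)):min(d[1] - 1L, ceiling(d[1] * 0.75))
  ys <- max(2L, floor(d[2] * 0.25)):min(d[2] - 1L, ceiling(d[2] * 0.75))
  zs <- max(3L, ceiling(d[3] * 0.4)):d[3]   # slices 1-2 reserved for CSF
  gm[xs, ys, zs] <- TRUE
  csf <- array(FALSE, dim = d)
  cx <- max(1L, floor(d[1] * 0.4)):min(d[1], ceiling(d[1] * 0.6))
  cz <- if (csf_in_bottom_slice) 1L else 2L
  csf[cx, cx, cz] <- TRUE
  if (any(gm & csf)) stop("grey-matter and CSF masks overlap")
  list(gm = mask_volume(gm, config$voxel_size_mm),
       csf = mask_volume(csf, config$voxel_size_mm))
}

#' Render a subject's signals into a 4D volume plus masks
#'
#' Grey-matter voxels carry the gBOLD signal plus independent voxel
#' noise; CSF voxels in the bottom slice carry the CSF signal plus
#' voxel noise; all remaining voxels are pure noise.
#'
#' @param signals output of [generate_signal_pair()].
#' @param config a [synthetic_config()].
#' @param seed RNG seed for the voxel noise.
#' @param csf_in_bottom_slice set `FALSE` to place the CSF region
#'   outside the reference slice (a coverage-failure fixture).
#' @return list with `vol` ([volume4d()]), `gm_mask`, `csf_mask`.
#' @export
render_nifti <- function(signals, config, seed = config$seed,
                         csf_in_bottom_slice = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  masks <- default_masks(config, csf_in_bottom_slice)
  d <- config$grid_dim
  nt <- length(signals$gbold$values)
  nvox <- prod(d)
  arr <- with_local_seed(seed, {
    a <- array(stats::rnorm(nvox * nt, sd = max(config$voxel_noise_sd, 1e-12)),
               dim = c(d, nt))
    flat <- matrix(a, nrow = nvox)
    if (config$voxel_noise_sd == 0) flat[] <- 0
    gidx <- which(masks$gm$data)
    cidx <- which(masks$csf$data)
    flat[gidx, ] <- flat[gidx, ] +
      rep(signals$gbold$values, each = length(gidx))
    flat[cidx, ] <- flat[cidx, ] +
      rep(signals$csf$values, each = length(cidx))
    array(flat, dim = c(d, nt))
  })
  list(vol = volume4d(arr, config$voxel_size_mm, config$tr),
       gm_mask = masks$gm, csf_mask = masks$csf)
}
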