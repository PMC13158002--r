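# Detrending, band-pass, smoothing, mask extraction, z-scoring,
# derivative, and the assembled per-subject pipeline.

test_that("detrend removes polynomials exactly and matches the LS oracle", {
  tt <- seq_len(50)
  quad <- time_series(3 + 0.5 * tt - 0.02 * tt^2, dt = 2)
  expect_lt(max(abs(detrend(quad, 2)$values)), 1e-9)
  expect_lt(max(abs(detrend(time_series(rep(7, 20), 2))$values)), 1e-12)

  set.seed(4)
  for (degree in 1:2) {
    y <- rnorm(60)
    got <- detrend(time_series(y, 2), degree)$values
    # independent normal-equations polynomial regression
    X <- outer(seq_len(60) / 60, 0:degree, `^`)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(got, as.numeric(y - X %*% beta), tolerance = 1e-9)
    # orthogonality of the residual to the basis
    expect_lt(max(abs(t(X) %*% got)), 1e-6 * sqrt(sum(y^2)))
  }
  expect_error(detrend(time_series(1:3, 1), 2), "too short")
})

test_that("band-pass passes in-band and rejects out-of-band sinusoids", {
  dt <- 2; n <- 800
  tt <- (0:(n - 1)) * dt
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- bandpass(time_series(x, dt))$values
    core <- 100:(n - 100)          # avoid edge transients
    max(abs(y[core])) / max(abs(x[core]))
  }
  expect_gt(amp_ratio(0.05), 0.9)     # mid-band
  expect_gt(amp_ratio(0.02), 0.9)
  expect_lt(amp_ratio(0.005), 0.1)    # half the low edge
  expect_lt(amp_ratio(0.2), 0.1)      # twice the high edge
  expect_equal(bandpass(time_series(rep(0, 100), dt))$values, rep(0, 100))
})

test_that("band-pass is zero-phase", {
  set.seed(5)
  # time reversal commutes with filtering up to edge-padding effects
  x <- rnorm(300)
  f1 <- bandpass(time_series(x, 2))$values
  f2 <- rev(bandpass(time_series(rev(x), 2))$values)
  core <- 60:240    # the 0.01 Hz edge has a ~100 s transient scale
  expect_lt(sqrt(mean((f1 - f2)[core]^2)) / sqrt(mean(f1[core]^2)), 0.02)
  # no group delay: an in-band sinusoid keeps its phase exactly
  tt <- (0:799) * 2
  s <- sin(2 * pi * 0.04 * tt)
  y <- bandpass(time_series(s, 2))$values
  core <- 100:700
  expect_equal(cor(y[core], s[core]), 1, tolerance = 1e-6)
})

test_that("band-pass rejects invalid edges", {
  expect_error(bandpass(time_series(rnorm(100), 2),
                        filter_spec(0.01, 0.3)), "Nyquist")
  expect_error(filter_spec(0.1, 0.01))
})

test_that("Gaussian smoothing has the requested width and conserves mass", {
  dims <- c(17, 17, 17)   # impulse far enough from edges that the
  arr <- array(0, dim = c(dims, 2))  # truncated kernel never touches them
  arr[9, 9, 9, ] <- 1
  vol <- volume4d(arr, voxel_size = c(2, 2, 2), tr = 2)
  sm <- smooth_gaussian(vol, smooth_spec(fwhm_mm = 4))
  # mass conservation for an interior impulse
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 1e-6)
  # half-maximum width along x ~ 4 mm = 2 voxels (discrete-kernel width
  # computed from the profile by linear interpolation)
  prof <- sm$data[, 9, 9, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  frac_lo <- (prof[lo] - half) / (prof[lo] - prof[lo - 1])
  frac_hi <- (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_vox <- (hi + frac_hi) - (lo - frac_lo)
  expect_equal(fwhm_vox, 2, tolerance = 0.25)

  const <- volume4d(array(3.7, dim = c(6, 6, 4, 2)), c(3, 3, 3), 2)
  expect_equal(smooth_gaussian(const)$data, const$data, tolerance = 1e-12)
  expect_identical(smooth_gaussian(vol, smooth_spec(0)), vol)
})

test_that("extract_mean_series equals the per-voxel loop oracle", {
  vol <- random_volume(dims = c(5, 4, 3), nt = 20, seed = 6)
  mask <- random_mask(dims = c(5, 4, 3), seed = 7)
  got <- extract_mean_series(vol, mask)
  idx <- which(mask$data, arr.ind = TRUE)
  oracle <- sapply(seq_len(20), function(t) {
    acc <- 0
    for (r in seq_len(nrow(idx))) acc <- acc + vol$data[idx[r, 1], idx[r, 2], idx[r, 3], t]
    acc / nrow(idx)
  })
  expect_equal(got$values, oracle, tolerance = 1e-12)
  expect_equal(got$dt, vol$tr)

  one <- mask_volume(array(c(1, rep(0, 59)), dim = c(5, 4, 3)), c(3, 3, 3.5))
  expect_equal(extract_mean_series(vol, one)$values, vol$data[1, 1, 1, ])
})

test_that("extract_mean_series is linear and cancels opposite signals", {
  vol1 <- random_volume(dims = c(4, 4, 2), nt = 15, seed = 8)
  vol2 <- random_volume(dims = c(4, 4, 2), nt = 15, seed = 9)
  mask <- random_mask(dims = c(4, 4, 2), seed = 10)
  combo <- volume4d(2 * vol1$data - 3 * vol2$data, vol1$voxel_size, 2)
  expect_equal(extract_mean_series(combo, mask)$values,
               2 * extract_mean_series(vol1, mask)$values -
                 3 * extract_mean_series(vol2, mask)$values,
               tolerance = 1e-12)

  s <- rnorm(12)
  arr <- array(0, dim = c(2, 1, 1, 12))
  arr[1, 1, 1, ] <- s; arr[2, 1, 1, ] <- -s
  both <- mask_volume(array(1, dim = c(2, 1, 1)), c(3, 3, 3))
  expect_equal(extract_mean_series(volume4d(arr, c(3, 3, 3), 2), both)$values,
               rep(0, 12))
})

test_that("extract_csf_series uses the reference slice only and flags coverage", {
  vol <- random_volume(dims = c(4, 4, 3), nt = 16, seed = 11)
  m <- array(0, dim = c(4, 4, 3))
  m[2, 2, 1] <- 1; m[3, 3, 1] <- 1
  m[1, 1, 3] <- 1                       # outside the bottom slice: ignored
  csf <- mask_volume(m, c(3, 3, 3.5))
  got <- extract_csf_series(vol, csf)
  expect_equal(got$values,
               (vol$data[2, 2, 1, ] + vol$data[3, 3, 1, ]) / 2,
               tolerance = 1e-12)

  mtop <- mask_volume(array(c(rep(0, 32), rep(1, 16)), dim = c(4, 4, 3)),
                      c(3, 3, 3.5))
  err <- tryCatch(extract_csf_series(vol, mtop), condition = identity)
  expect_s3_class(err, "csf_coverage_error")

  one <- array(0, dim = c(4, 4, 3)); one[1, 2, 1] <- 1
  expect_equal(extract_csf_series(vol, mask_volume(one, c(3, 3, 3.5)),
                                  csf_roi_spec(min_voxels = 1))$values,
               vol$data[1, 2, 1, ])
})

test_that("zscore standardizes, is idempotent, and rejects constants", {
  z <- zscore(time_series(c(1, 2, 3), 1))
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$values^2)), 1, tolerance = 1e-12)
  expect_true(z$standardized)
  expect_equal(zscore(z)$values, z$values, tolerance = 1e-12)
  expect_error(zscore(time_series(rep(2, 10), 1)), "constant")
})

test_that("negative_derivative matches analytic derivatives", {
  ramp <- time_series(5 + 3 * (0:19) * 2, dt = 2)  # slope +3 per second
  nd <- negative_derivative(ramp)
  expect_equal(nd$values, rep(-3, 19), tolerance = 1e-12)
  expect_equal(length(nd$values), 19)
  expect_equal(nd$t0, 1)                            # half-sample shift recorded

  expect_lt(max(abs(negative_derivative(time_series(rep(1, 10), 2))$values)), 1e-12)

  f <- 0.03; dt <- 0.5
  tt <- (0:399) * dt
  nd <- negative_derivative(time_series(sin(2 * pi * f * tt), dt))
  mid <- tt[-length(tt)] + dt / 2
  expect_equal(nd$values, -2 * pi * f * cos(2 * pi * f * mid),
               tolerance = (2 * pi * f * dt)^2)
})

test_that("detrend and bandpass nearly commute (documented order check)", {
  # The operators commute in the long-series limit; at scan length the
  # polynomial fit of a band-passed finite sample is not negligible,
  # which is exactly why the pipeline fixes the order (detrend first).
  set.seed(12)
  for (rep in 1:3) {
    x <- time_series(rnorm(4000), 2)
    a <- bandpass(detrend(x))$values
    b <- detrend(bandpass(x))$values
    expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(b^2)), 0.02)
  }
})

test_that("subject_pipeline produces aligned z-scored series and QC verdicts", {
  cfg <- synthetic_config(n_bqd = 2, n_hc = 2, n_volumes = 240,
                          grid_dim = c(8, 8, 4), seed = 21)
  pair <- generate_signal_pair(cfg, -0.5, seed = 3)
  rend <- render_nifti(pair, cfg, seed = 4)
  clean <- motion_trace(matrix(0.1, 240, 3), matrix(0.05, 240, 3))
  res <- subject_pipeline(rend$vol, rend$gm_mask, rend$csf_mask, clean)
  expect_false(res$excluded)
  expect_equal(length(res$gbold$values), 230)
  expect_equal(length(res$csf$values), 230)
  expect_equal(res$gbold$dt, 2)
  expect_true(res$gbold$standardized && res$csf$standardized)

  bad <- motion_trace(matrix(c(rep(0.1, 719), 1.6), 240, 3),
                      matrix(0.05, 240, 3))
  res2 <- subject_pipeline(rend$vol, rend$gm_mask, rend$csf_mask, bad)
  expect_true(res2$excluded)
  expect_equal(res2$exclude_reason, "motion")

  rend3 <- render_nifti(pair, cfg, seed = 4, csf_in_bottom_slice = FALSE)
  res3 <- subject_pipeline(rend3$vol, rend3$gm_mask, rend3$csf_mask, clean)
  expect_true(res3$excluded)
  expect_equal(res3$exclude_reason, "csf_coverage")
})

test_that("correlation of z-scored series is affine-invariant", {
  set.seed(13)
  x <- rnorm(100); y <- rnorm(100)
  r1 <- cor(zscore(time_series(x, 2))$values, zscore(time_series(y, 2))$values)
  r2 <- cor(zscore(time_series(5 * x - 2, 2))$values,
            zscore(time_series(-0.3 * y + 11, 2))$values)
  expect_equal(abs(r1), abs(r2), tolerance = 1e-12)
})
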