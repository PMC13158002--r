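# Screening, the demographic tests, the group contrasts, and the
# clinical correlation analysis.

make_records <- function(n_bqd = 6, n_hc = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("s%02d", 1:(n_bqd + n_hc)),
    group = rep(c("BQD", "HC"), c(n_bqd, n_hc)),
    sex = sample(c("M", "F"), n_bqd + n_hc, replace = TRUE),
    age = sample(20:55, n_bqd + n_hc, replace = TRUE),
    education = sample(6:18, n_bqd + n_hc, replace = TRUE),
    bqds = c(runif(n_bqd, 5, 14), rep(NA, n_hc)),
    duration = c(runif(n_bqd, 2, 30), rep(NA, n_hc)),
    daily_dose = c(runif(n_bqd, 1, 20), rep(NA, n_hc)),
    hama14 = sample(0:6, n_bqd + n_hc, replace = TRUE),
    hamd24 = sample(0:6, n_bqd + n_hc, replace = TRUE),
    coupling = rnorm(n_bqd + n_hc, -0.17, 0.2),
    qc_pass = TRUE,
    stringsAsFactors = FALSE)
}

test_that("screen_participants applies the strict boundary rules", {
  rec <- data.frame(
    id = paste0("s", 1:6),
    group = c("BQD", "BQD", "BQD", "BQD", "HC", "HC"),
    age = c(30, 30, 61, 30, 30, 17),
    bqds = c(4, 5, 8, 9, NA, NA),
    hama14 = c(2, 3, 1, 2, NA, NA),
    hamd24 = c(3, 7, 2, 8, NA, NA),
    stringsAsFactors = FALSE)
  out <- screen_participants(rec)
  # bqds = 4 excluded (strictly greater than 4 required)
  expect_true("s1" %in% out$excluded$id)
  expect_equal(out$excluded$reason[out$excluded$id == "s1"], "bqds")
  # hamd24 = 7 included ("not exceeding 7")
  expect_true("s2" %in% out$included$id)
  # age 61 excluded
  expect_equal(out$excluded$reason[out$excluded$id == "s3"], "age")
  # hamd24 = 8 excluded
  expect_equal(out$excluded$reason[out$excluded$id == "s4"], "hamd24")
  # HC kept on age alone; age 17 excluded
  expect_true("s5" %in% out$included$id)
  expect_equal(out$excluded$reason[out$excluded$id == "s6"], "age")

  miss <- data.frame(id = "x", group = "BQD", age = 30, bqds = NA,
                     hama14 = 1, hamd24 = 1, stringsAsFactors = FALSE)
  expect_equal(screen_participants(miss)$excluded$reason, "missing:bqds")
})

test_that("chi_square_2x2 matches the closed form and stats::chisq.test", {
  got <- chi_square_2x2(13, 16, 5, 32)
  # hand-computed: 66*(13*32 - 16*5)^2 / (29*37*18*48)
  expect_equal(got$chi2, 66 * (13 * 32 - 16 * 5)^2 / (29 * 37 * 18 * 48),
               tolerance = 1e-12)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(13, 5, 16, 32), 2), correct = FALSE))
  expect_equal(got$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(round(got$p, 3), 0.005)

  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  # symmetry: swapping rows, and transposing, leave chi2 unchanged
  expect_equal(chi_square_2x2(5, 32, 13, 16)$chi2, got$chi2)
  expect_equal(chi_square_2x2(13, 5, 16, 32)$chi2, got$chi2)
  expect_error(chi_square_2x2(0, 0, 3, 4), "zero margin")
})

test_that("mann_whitney: exact enumeration, ties, and symmetry", {
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)          # 2/20 rank splits are as extreme
  expect_equal(sep$method, "exact enumeration")

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)           # n1*n2/2 with full ties
  expect_gt(same$p, 0.9)

  set.seed(31)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$U, 20 * 25 - b$U)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  # normal-approximation path against the R oracle
  oracle <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = FALSE))
  expect_equal(a$U, unname(oracle$statistic))
  expect_equal(a$p, oracle$p.value, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("ttest_from_summary reproduces the pooled t and the R oracle", {
  got <- ttest_from_summary(-0.240, 0.200, 29, -0.111, 0.225, 37)
  expect_equal(got$df, 64)
  expect_equal(got$t, -2.42578, tolerance = 1e-5)
  expect_equal(got$variant, "pooled")

  eq <- ttest_from_summary(1.3, 0.5, 10, 1.3, 0.5, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  # moment-matched raw data must give the identical pooled t
  set.seed(32)
  for (rep in 1:3) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x <- as.numeric(scale(rnorm(n1))) * 0.7 + 0.2
    y <- as.numeric(scale(rnorm(n2))) * 1.1 - 0.1
    ora <- stats::t.test(x, y, var.equal = TRUE)
    via <- ttest_from_summary(mean(x), sd(x), n1, mean(y), sd(y), n2)
    expect_equal(via$t, unname(ora$statistic), tolerance = 1e-9)
    expect_equal(via$p, ora$p.value, tolerance = 1e-9)
  }
  expect_error(ttest_from_summary(0, 0.1, 1, 0, 0.1, 5), "n >= 2")
  expect_error(ttest_from_summary(0, 0, 5, 0, 0.1, 5), "positive")
})

test_that("group_ttest is consistent with its own summaries", {
  rec <- make_records(10, 12, seed = 33)
  got <- group_ttest(rec)
  again <- ttest_from_summary(got$mean_sd$group1[["mean"]],
                              got$mean_sd$group1[["sd"]], got$n[["n1"]],
                              got$mean_sd$group2[["mean"]],
                              got$mean_sd$group2[["sd"]], got$n[["n2"]])
  expect_equal(got$t, again$t, tolerance = 1e-12)

  rec2 <- make_records(8, 8, seed = 34)
  rec2$coupling <- rep(c(-0.2, -0.1), 8)   # identical group compositions
  expect_equal(group_ttest(rec2)$t, 0, tolerance = 1e-9)

  rec3 <- make_records(4, 4)
  rec3$qc_pass <- c(TRUE, FALSE, FALSE, FALSE, rep(TRUE, 4))
  expect_error(group_ttest(rec3), ">= 2 QC-passing")
})

test_that("adjusted_group_model: OLS equivalence, confounding, rank checks", {
  rec <- make_records(15, 15, seed = 35)
  # no covariates: t equals the pooled two-sample t exactly
  adj0 <- adjusted_group_model(rec, covariates = character(0))
  expect_equal(adj0$t, group_ttest(rec)$t, tolerance = 1e-9)

  # covariates independent of group/outcome: estimate ~ raw difference
  set.seed(36)
  n <- 400
  big <- data.frame(group = rep(c("BQD", "HC"), each = n / 2),
                    sex = sample(c("M", "F"), n, TRUE),
                    age = runif(n, 20, 60), education = runif(n, 6, 18))
  big$coupling <- -0.2 + 0.1 * (big$group == "BQD") + rnorm(n, sd = 0.1)
  adj <- adjusted_group_model(big)
  raw_diff <- mean(big$coupling[big$group == "BQD"]) -
    mean(big$coupling[big$group == "HC"])
  expect_equal(adj$estimate, raw_diff, tolerance = 0.02)

  # outcome fully carried by a confounded covariate -> estimate ~ 0
  conf <- big
  conf$age <- 40 + 10 * (conf$group == "BQD") + rnorm(n)
  conf$coupling <- -0.01 * conf$age + rnorm(n, sd = 0.01)
  adjc <- adjusted_group_model(conf, covariates = "age")
  expect_lt(abs(adjc$estimate), 0.02)

  degen <- rec; degen$education <- 12
  expect_error(adjusted_group_model(degen), "education")
})

test_that("clinical_correlations: t-transform p, Bonferroni flags", {
  # r = 0.4313 at n = 29 gives uncorrected p ~ 0.0195
  expect_equal(round(csfcoupling:::pearson_p(0.4313, 29), 4), 0.0195)

  rec <- make_records(12, 10, seed = 37)
  out <- clinical_correlations(rec)
  expect_equal(nrow(out), 5)
  expect_equal(unique(out$corrected_threshold), 0.01)
  expect_identical(unique(out$corrected_threshold * out$m_tests), 0.05)
  # oracle: cor.test on the same pairs
  bqd <- rec[rec$group == "BQD", ]
  ora <- stats::cor.test(bqd$coupling, bqd$duration)
  i <- out$variable == "duration"
  expect_equal(out$r[i], unname(ora$estimate), tolerance = 1e-10)
  expect_equal(out$p_uncorrected[i], ora$p.value, tolerance = 1e-10)
  expect_identical(out$significant_after_correction,
                   out$p_uncorrected < 0.01)

  # a perfectly linear variable: r = 1, p ~ 0, flagged
  lin <- rec; lin$duration[lin$group == "BQD"] <-
    2 * lin$coupling[lin$group == "BQD"] + 5
  lout <- clinical_correlations(lin)
  expect_equal(lout$r[lout$variable == "duration"], 1, tolerance = 1e-9)
  expect_true(lout$significant_after_correction[lout$variable == "duration"])

  # constant variable -> not computable
  const <- rec; const$bqds[const$group == "BQD"] <- 7
  cout <- clinical_correlations(const)
  expect_true(is.na(cout$r[cout$variable == "bqds"]))
})

test_that("correlation flags are monotone in |r| at fixed n", {
  n <- 20
  ps <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), csfcoupling:::pearson_p, n = n)
  expect_true(all(diff(ps) < 0))
})

test_that("effect_size_r2 squares the correlation", {
  expect_equal(round(effect_size_r2(0.4313), 3), 0.186)
  expect_equal(effect_size_r2(0), 0)
  expect_equal(effect_size_r2(-1), 1)
  expect_error(effect_size_r2(1.2), "<= 1")
})

test_that("group_ttest holds its type-I error on null generator cohorts", {
  # equal group targets -> no true difference; the rejection rate at
  # alpha = 0.05 must sit inside a wide binomial band (99.9% interval)
  n_rep <- 100
  rejections <- sum(sapply(seq_len(n_rep), function(s) {
    cfg <- synthetic_config(n_bqd = 10, n_hc = 10, n_volumes = 120,
                            target_coupling = c(bqd = -0.17, hc = -0.17),
                            coupling_sd = c(bqd = 0.2, hc = 0.2),
                            seed = 5000 + s)
    coh <- generate_cohort(cfg)
    est <- vapply(coh$signals, function(p) {
      cc <- cross_correlation(p$gbold, p$csf)
      as.numeric(coupling_strength(cc))
    }, numeric(1))
    rec <- data.frame(group = coh$records$group, coupling = est)
    group_ttest(rec)$p < 0.05
  }))
  lims <- qbinom(c(0.0005, 0.9995), n_rep, 0.05)
  expect_gte(rejections, lims[1])
  expect_lte(rejections, lims[2])
})
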