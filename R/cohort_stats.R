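# Screening, demographics tests, group comparison and clinical
# correlations with Bonferroni control.
#
# Test choices mirror the analysis plan the metric is normally
# reported with: Pearson chi-square without continuity correction for
# sex, Mann-Whitney for non-normal continuous demographics, a
# pooled-variance two-sample t for the coupling contrast, OLS with
# sex/age/education covariates for the adjusted contrast, and Pearson
# correlations against clinical scores compared to a fixed alpha/m
# threshold.

#' Eligibility rules for cohort screening
#'
#' @param min_age,max_age age window (default 18-60, both arms).
#' @param bqds_min_exclusive dependence requires a BQDS score strictly
#'   greater than this (default 4).
#' @param hama_max,hamd_max maximum anxiety/depression scores, BQD arm
#'   (default 7, inclusive).
#' @return an `eligibility_rules` list.
#' @export
eligibility_rules <- function(min_age = 18, max_age = 60,
                              bqds_min_exclusive = 4, hama_max = 7,
                              hamd_max = 7) {
  if (min_age >= max_age) stop("min_age must be < max_age")
  structure(list(min_age = min_age, max_age = max_age,
                 bqds_min_exclusive = bqds_min_exclusive,
                 hama_max = hama_max, hamd_max = hamd_max),
            class = "eligibility_rules")
}

#' Screen participants against the eligibility rules
#'
#' BQD arm: kept iff `bqds > 4`, `hamd24 <= 7`, `hama14 <= 7` and age
#' within bounds.  HC arm: kept iff age within bounds.  Missing
#' required fields exclude with reason `"missing:<field>"`.
#'
#' @param records data.frame with at least `id`, `group`, `age`, and
#'   for the BQD arm `bqds`, `hama14`, `hamd24`.
#' @param rules an [eligibility_rules()].
#' @return list with `included` (data.frame) and `excluded`
#'   (data.frame with a `reason` column; one row per subject).
#' @export
screen_participants <- function(records, rules = eligibility_rules()) {
  stopifnot(is.data.frame(records), inherits(rules, "eligibility_rules"))
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    required <- if (r$group == "BQD") c("age", "bqds", "hama14", "hamd24")
                else "age"
    miss <- required[vapply(required, function(f)
      is.null(r[[f]]) || is.na(r[[f]]), logical(1))]
    if (length(miss)) { reason[i] <- paste0("missing:", miss[1]); next }
    if (r$age < rules$min_age || r$age > rules$max_age) {
      reason[i] <- "age"; next
    }
    if (r$group == "BQD") {
      if (r$bqds <= rules$bqds_min_exclusive) { reason[i] <- "bqds"; next }
      if (r$hamd24 > rules$hamd_max) { reason[i] <- "hamd24"; next }
      if (r$hama14 > rules$hama_max) { reason[i] <- "hama14"; next }
    }
  }
  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(included = records[keep, , drop = FALSE], excluded = excluded)
}

#' Pearson chi-square on a 2x2 table, no continuity correction
#'
#' @param a,b,c,d cell counts, rows = groups, columns = categories.
#' @return list with `chi2`, `df` (1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) stop("zero margin in 2x2 table")
  chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration of all rank splits when
#' `n1 + n2 <= 12`; otherwise the normal approximation with tie
#' correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("empty sample")
  ranks <- rank(c(x, y))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 12L) {
    combos <- utils::combn(n1 + n2, n1)
    stats_all <- apply(combos, 2, function(idx) sum(ranks[idx])) -
      n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(stats_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(ranks)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Pooled-variance two-sample t from group summaries
#'
#' @param mean1,sd1,n1 first-group summary (n >= 2, sd > 0).
#' @param mean2,sd2,n2 second-group summary.
#' @return list with `t`, `df` (`n1 + n2 - 2`), `p` (two-sided),
#'   `mean_sd` per group, `n` per group, `variant` (`"pooled"`).
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_sd = list(group1 = c(mean = mean1, sd = sd1),
                      group2 = c(mean = mean2, sd = sd2)),
       n = c(n1 = n1, n2 = n2), variant = "pooled")
}

#' Pooled two-sample t on per-subject coupling strengths
#'
#' Compares the BQD and HC coupling values of QC-passing subjects.
#'
#' @param records data.frame with `group`, `coupling` and optionally
#'   `qc_pass` (non-TRUE rows dropped when present).
#' @return as [ttest_from_summary()], group1 = BQD, group2 = HC.
#' @export
group_ttest <- function(records) {
  stopifnot(is.data.frame(records))
  if (!is.null(records$qc_pass)) records <- records[records$qc_pass %in% TRUE, ]
  records <- records[!is.na(records$coupling), ]
  x <- records$coupling[records$group == "BQD"]
  y <- records$coupling[records$group == "HC"]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 QC-passing coupling values")
  ttest_from_summary(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y))
}

#' Covariate-adjusted group contrast (OLS)
#'
#' Ordinary least squares of coupling on a group indicator
#' (BQD = 1, HC = 0) plus covariates; sex is coded 0/1 (reference
#' `"F"` by default), age and education enter linearly.
#'
#' @param records data.frame with `group`, `coupling`, covariates.
#' @param covariates character vector (default sex, age, education).
#' @param sex_reference sex level coded 0 (default `"F"`).
#' @return list with the full `coefficients` table and the group
#'   row expanded as `estimate`, `se`, `t`, `p`, plus `n`.
#' @export
adjusted_group_model <- function(records,
                                 covariates = c("sex", "age", "education"),
                                 sex_reference = "F") {
  stopifnot(is.data.frame(records))
  if (!is.null(records$qc_pass)) records <- records[records$qc_pass %in% TRUE, ]
  records <- records[!is.na(records$coupling), ]
  dat <- data.frame(coupling = records$coupling,
                    group_bqd = as.numeric(records$group == "BQD"))
  for (cv in covariates) {
    if (is.null(records[[cv]])) stop(sprintf("missing covariate column: %s", cv))
    v <- records[[cv]]
    if (cv == "sex") v <- as.numeric(v != sex_reference)
    v <- as.numeric(v)
    if (stats::sd(v) == 0)
      stop(sprintf("rank deficiency: covariate `%s` has zero variance", cv))
    dat[[cv]] <- v
  }
  if (nrow(dat) <= ncol(dat) + 1L) stop("too few subjects for the model")
  fit <- stats::lm(coupling ~ ., data = dat)
  qr_rank <- fit$rank
  if (qr_rank < ncol(dat))
    stop("rank-deficient design: a covariate is collinear")
  ct <- summary(fit)$coefficients
  g <- ct["group_bqd", ]
  list(coefficients = ct, estimate = unname(g[1]), se = unname(g[2]),
       t = unname(g[3]), p = unname(g[4]), n = nrow(dat))
}

#' Pearson correlations of coupling with clinical variables
#'
#' BQD arm only.  For each variable, pairwise-complete Pearson r and
#' the exact t-transform p (`t = r sqrt(n-2)/sqrt(1-r^2)`, df = n-2,
#' two-sided).  Multiplicity is controlled by a fixed Bonferroni
#' threshold: each uncorrected p is compared against `alpha / m`
#' (strict `<`), where `m` is the number of variables tested.
#'
#' @param records data.frame with `group`, `coupling` and the clinical
#'   columns.
#' @param variables clinical columns to test (default the five:
#'   bqds, duration, daily_dose, hama14, hamd24).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame, one row per variable: `variable`, `r`, `n`,
#'   `p_uncorrected`, `m_tests`, `alpha`, `corrected_threshold`,
#'   `significant_after_correction`.
#' @export
clinical_correlations <- function(records,
                                  variables = c("bqds", "duration",
                                                "daily_dose", "hama14",
                                                "hamd24"),
                                  alpha = 0.05) {
  stopifnot(is.data.frame(records))
  if (!is.null(records$qc_pass)) records <- records[records$qc_pass %in% TRUE, ]
  bqd <- records[records$group == "BQD" & !is.na(records$coupling), ]
  m <- length(variables)
  thr <- alpha / m
  out <- lapply(variables, function(v) {
    if (is.null(bqd[[v]]))
      stop(sprintf("missing clinical column: %s", v))
    ok <- !is.na(bqd[[v]])
    n <- sum(ok)
    if (n < 3L || stats::sd(bqd[[v]][ok]) == 0) {
      return(data.frame(variable = v, r = NA_real_, n = n,
                        p_uncorrected = NA_real_, m_tests = m, alpha = alpha,
                        corrected_threshold = thr,
                        significant_after_correction = NA))
    }
    r <- stats::cor(bqd$coupling[ok], bqd[[v]][ok])
    p <- pearson_p(r, n)
    data.frame(variable = v, r = r, n = n, p_uncorrected = p, m_tests = m,
               alpha = alpha, corrected_threshold = thr,
               significant_after_correction = p < thr)
  })
  do.call(rbind, out)
}

pearson_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), n - 2)
}

#' Squared correlation effect size
#' @param r Pearson correlation, `|r| <= 1`.
#' @return `r^2`.
#' @export
effect_size_r2 <- function(r) {
  if (!is.numeric(r) || any(abs(r) > 1)) stop("|r| must be <= 1")
  r^2
}
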