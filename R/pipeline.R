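# Stage orchestration: simulate -> extract -> couple -> stats, with
# plain TSV/JSON artifacts between stages so any stage can be rerun
# or replaced independently.

#' Pipeline run configuration
#'
#' @param study_dir directory holding (or to hold) the study: volumes,
#'   masks, motion files, cohort table; stage outputs are written to
#'   `extract/`, `couple/`, `stats/` inside it.
#' @param synthetic a [synthetic_config()] (used by [run_simulate()]).
#' @param pipeline a [pipeline_config()].
#' @param coupling a [coupling_config()].
#' @param n_iter permutation iterations (default 10000).
#' @param alpha family-wise level for the clinical correlations.
#' @param covariates adjusted-model covariates.
#' @param seed master seed for stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(study_dir, synthetic = synthetic_config(),
                       pipeline = pipeline_config(),
                       coupling = coupling_config(), n_iter = 10000,
                       alpha = 0.05,
                       covariates = c("sex", "age", "education"),
                       seed = 1) {
  structure(list(study_dir = study_dir, synthetic = synthetic,
                 pipeline = pipeline, coupling = coupling, n_iter = n_iter,
                 alpha = alpha, covariates = covariates, seed = seed),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' The file may set any subset of the nested fields; unset fields keep
#' their defaults.
#'
#' @param path JSON file.
#' @param study_dir override for the study directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, study_dir = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- do.call(synthetic_config, raw$synthetic %||% list())
  pl <- pipeline_config(
    qc = do.call(qc_policy, raw$qc %||% list()),
    filter = do.call(filter_spec, raw$filter %||% list()),
    smooth = do.call(smooth_spec, raw$smooth %||% list()),
    csf_roi = do.call(csf_roi_spec, raw$csf_roi %||% list()))
  run_config(study_dir = study_dir %||% raw$study_dir,
             synthetic = syn, pipeline = pl,
             coupling = do.call(coupling_config, raw$coupling %||% list()),
             n_iter = raw$n_iter %||% 10000,
             alpha = raw$alpha %||% 0.05,
             covariates = raw$covariates %||% c("sex", "age", "education"),
             seed = raw$seed %||% 1)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

log_info <- function(fmt, ...) {
  message(sprintf(paste0("[csfcoupling] ", fmt), ...))
}

#' Stage 1: write a synthetic study directory
#'
#' Generates a cohort ([generate_cohort()]), renders every subject's
#' 4D NIfTI volume, writes shared grey-matter and CSF masks, rp-style
#' motion files, the cohort TSV, the ground-truth JSON, the generator
#' config, and a manifest with file checksums.
#'
#' @param config a [run_config()].
#' @return the study directory, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$study_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  syn <- config$synthetic
  log_info("simulating cohort: %d BQD + %d HC subjects, %d volumes, TR %gs",
           syn$n_bqd, syn$n_hc, syn$n_volumes, syn$tr)
  coh <- generate_cohort(syn)
  masks <- default_masks(syn)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  write_nifti(masks$gm, file.path(dir, "masks", "gm.nii.gz"))
  write_nifti(masks$csf, file.path(dir, "masks", "csf.nii.gz"))
  for (i in seq_len(nrow(coh$records))) {
    id <- coh$records$id[i]
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    rend <- render_nifti(coh$signals[[i]], syn,
                         seed = derive_seed(syn$seed, 2L * i + 100000L))
    write_nifti(rend$vol, file.path(sdir, "func.nii.gz"))
    write_motion_params(coh$motion[[i]], file.path(sdir, "rp.txt"))
  }
  write_tsv(coh$records[, setdiff(names(coh$records),
                                  c("coupling", "qc_pass"))],
            file.path(dir, "cohort.tsv"))
  write_json_file(coh$ground_truth, file.path(dir, "ground_truth.json"))
  write_json_file(unclass(syn), file.path(dir, "config.json"))
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  log_info("study written to %s (%d files)", dir, nrow(manifest) + 1L)
  invisible(dir)
}

#' Stage 2: preprocess every subject and extract signal series
#'
#' Runs [subject_pipeline()] per subject: motion QC, volume discard,
#' detrending, band-pass, smoothing, mask averaging.  Writes
#' two-column TSV series (`time_s`, `value`) per included subject, a
#' QC report and an exclusion log with machine-readable reasons
#' (`motion`, `csf_coverage`, `missing_files`).
#'
#' @param config a [run_config()].
#' @return data.frame QC report, invisibly.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$study_dir
  cohort <- read_tsv(file.path(dir, "cohort.tsv"))
  outdir <- file.path(dir, "extract")
  dir.create(file.path(outdir, "series"), recursive = TRUE, showWarnings = FALSE)
  qc_rows <- list(); excl_rows <- list()
  gm <- csf <- NULL
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$id[i]
    vol_path <- file.path(dir, id, "func.nii.gz")
    rp_path <- file.path(dir, id, "rp.txt")
    if (!file.exists(vol_path) || !file.exists(rp_path)) {
      log_info("%s: missing input files, skipped", id)
      excl_rows[[id]] <- data.frame(subject_id = id, reason = "missing_files")
      next
    }
    vol <- read_volume(vol_path)
    if (is.null(gm)) {
      gm <- read_mask(file.path(dir, "masks", "gm.nii.gz"), vol)
      csf <- read_mask(file.path(dir, "masks", "csf.nii.gz"), vol)
    }
    # per-subject mask overrides (e.g. field-of-view differences)
    gm_i <- gm; csf_i <- csf
    own_gm <- file.path(dir, id, "gm.nii.gz")
    own_csf <- file.path(dir, id, "csf.nii.gz")
    if (file.exists(own_gm)) gm_i <- read_mask(own_gm, vol)
    if (file.exists(own_csf)) csf_i <- read_mask(own_csf, vol)
    motion <- read_motion_params(rp_path)
    res <- subject_pipeline(vol, gm_i, csf_i, motion, config$pipeline)
    qc_rows[[id]] <- data.frame(subject_id = id,
                                max_trans_mm = res$qc$max_trans_mm,
                                max_rot_deg = res$qc$max_rot_deg,
                                pass = res$qc$pass)
    if (res$excluded) {
      log_info("%s: excluded (%s)", id, res$exclude_reason)
      excl_rows[[id]] <- data.frame(subject_id = id,
                                    reason = res$exclude_reason)
      next
    }
    tvec <- (seq_along(res$gbold$values) - 1L) * res$gbold$dt
    write_tsv(data.frame(time_s = tvec, value = res$gbold$values),
              file.path(outdir, "series", paste0(id, "_gbold.tsv")))
    write_tsv(data.frame(time_s = tvec, value = res$csf$values),
              file.path(outdir, "series", paste0(id, "_csf.tsv")))
  }
  qc <- do.call(rbind, qc_rows)
  write_tsv(qc, file.path(outdir, "qc_report.tsv"))
  excl <- if (length(excl_rows)) do.call(rbind, excl_rows)
          else data.frame(subject_id = character(), reason = character())
  write_tsv(excl, file.path(outdir, "exclusions.tsv"))
  log_info("extracted %d subjects, excluded %d",
           nrow(cohort) - nrow(excl), nrow(excl))
  invisible(qc)
}

read_series <- function(path) {
  tab <- read_tsv(path)
  dt <- stats::median(diff(tab$time_s))
  time_series(tab$value, dt)
}

#' Stage 3: coupling curves, metrics and the permutation null
#'
#' Computes per-subject cross-correlation and derivative-coupling
#' curves, the fixed-lag coupling strength, peak locations, the
#' group-mean curves, and the subject-shuffling permutation null of
#' the mean coupling statistic.
#'
#' @param config a [run_config()].
#' @return the metrics data.frame, invisibly.
#' @export
run_couple <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$study_dir
  sdir <- file.path(dir, "extract", "series")
  gfiles <- sort(list.files(sdir, pattern = "_gbold\\.tsv$", full.names = TRUE))
  ids <- sub("_gbold\\.tsv$", "", basename(gfiles))
  outdir <- file.path(dir, "couple")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  glist <- clist <- list()
  curve_rows <- list(); metric_rows <- list(); curves <- list(); dcurves <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    g <- read_series(gfiles[i])
    c <- read_series(file.path(sdir, paste0(id, "_csf.tsv")))
    glist[[id]] <- g; clist[[id]] <- c
    cc <- cross_correlation(g, c, config$coupling)
    dc <- derivative_coupling(g, c, config$coupling)
    curves[[id]] <- cc; dcurves[[id]] <- dc
    pk <- find_peaks(cc); dpk <- find_peaks(dc)
    strength <- coupling_strength(cc, config$coupling)
    curve_rows[[id]] <- data.frame(subject_id = id, lag_s = cc$lags_s, r = cc$r)
    metric_rows[[id]] <- data.frame(
      subject_id = id, strength = as.numeric(strength),
      pos_peak_lag = pk$pos_peak$lag_s, pos_peak_r = pk$pos_peak$r,
      neg_peak_lag = pk$neg_peak$lag_s, neg_peak_r = pk$neg_peak$r,
      deriv_peak_lag = dpk$pos_peak$lag_s, deriv_peak_r = dpk$pos_peak$r)
  }
  if (length(ids) == 0L) stop("no extracted series found; run extract first")
  write_tsv(do.call(rbind, curve_rows), file.path(outdir, "curves.tsv"))
  metrics <- do.call(rbind, metric_rows)
  write_tsv(metrics, file.path(outdir, "metrics.tsv"))
  mc <- group_mean_curve(curves); md <- group_mean_curve(dcurves)
  write_tsv(data.frame(lag_s = mc$lags_s, r = mc$r, deriv_r = md$r),
            file.path(outdir, "group_mean_curve.tsv"))
  if (length(ids) >= 3L) {
    null <- permutation_null(glist, clist, config$coupling,
                             n_iter = config$n_iter, seed = config$seed)
    write_tsv(data.frame(iteration = seq_len(null$n_iter), value = null$values),
              file.path(outdir, "null_values.tsv"))
    write_json_file(list(n_iter = null$n_iter, seed = null$seed,
                         observed = null$observed,
                         p_two_sided = null$p_two_sided),
                    file.path(outdir, "null_summary.json"))
    log_info("permutation null: observed=%.4f p=%.4g", null$observed,
             null$p_two_sided)
  } else {
    warning("fewer than 3 subjects: permutation null skipped")
  }
  log_info("coupling metrics written for %d subjects", length(ids))
  invisible(metrics)
}

#' Stage 4: cohort statistics report
#'
#' Demographics contrasts (chi-square for sex, Mann-Whitney for the
#' continuous variables), the raw pooled-t group comparison of
#' coupling, the covariate-adjusted OLS contrast, and the five
#' clinical Pearson correlations with the Bonferroni threshold.
#' Writes TSVs, a JSON mirror with identical numbers, and a plain-text
#' report.
#'
#' @param config a [run_config()].
#' @return the report list, invisibly.
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$study_dir
  cohort <- read_tsv(file.path(dir, "cohort.tsv"))
  metrics <- read_tsv(file.path(dir, "couple", "metrics.tsv"))
  qc <- read_tsv(file.path(dir, "extract", "qc_report.tsv"))
  records <- merge(cohort, metrics[, c("subject_id", "strength")],
                   by.x = "id", by.y = "subject_id", all.x = TRUE)
  records$coupling <- records$strength
  records$qc_pass <- records$id %in% qc$subject_id[qc$pass] &
    !is.na(records$coupling)
  outdir <- file.path(dir, "stats")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  sex_tab <- table(factor(records$group, c("BQD", "HC")),
                   factor(records$sex, c("M", "F")))
  chi <- tryCatch(chi_square_2x2(sex_tab[1, 1], sex_tab[1, 2],
                                 sex_tab[2, 1], sex_tab[2, 2]),
                  error = function(e) list(chi2 = NA_real_, p = NA_real_))
  demo_rows <- list(data.frame(variable = "sex", test = "chi-square",
                               statistic = chi$chi2, p = chi$p))
  for (v in c("age", "education", "hama14", "hamd24")) {
    mw <- mann_whitney(records[[v]][records$group == "BQD"],
                       records[[v]][records$group == "HC"])
    demo_rows[[v]] <- data.frame(variable = v, test = "mann-whitney",
                                 statistic = mw$U, p = mw$p)
  }
  demographics <- do.call(rbind, demo_rows)

  tt <- group_ttest(records)
  # degenerate small cohorts (zero-variance covariate, too few rows)
  # yield a missing adjusted model rather than a failed run
  adj <- tryCatch(adjusted_group_model(records, covariates = config$covariates),
                  error = function(e) {
    warning(sprintf("adjusted model not fitted: %s", conditionMessage(e)))
    list(estimate = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
         n = NA_integer_)
  })
  m_tests <- 5L
  corr <- clinical_correlations(records, alpha = config$alpha)

  write_tsv(demographics, file.path(outdir, "demographics.tsv"))
  group_tab <- data.frame(
    group = c("BQD", "HC"),
    n = c(tt$n[["n1"]], tt$n[["n2"]]),
    mean = c(tt$mean_sd$group1[["mean"]], tt$mean_sd$group2[["mean"]]),
    sd = c(tt$mean_sd$group1[["sd"]], tt$mean_sd$group2[["sd"]]))
  write_tsv(group_tab, file.path(outdir, "group_comparison.tsv"))
  write_tsv(corr, file.path(outdir, "clinical_correlations.tsv"))

  report <- list(
    demographics = demographics,
    group_comparison = list(groups = group_tab, t = tt$t, df = tt$df,
                            p = tt$p, variant = tt$variant),
    adjusted_model = list(estimate = adj$estimate, se = adj$se, t = adj$t,
                          p = adj$p, covariates = config$covariates,
                          n = adj$n),
    clinical_correlations = corr,
    bonferroni = list(alpha = config$alpha, m = m_tests,
                      corrected_threshold = config$alpha / m_tests))
  write_json_file(report, file.path(outdir, "report.json"))

  txt <- c(
    "Cohort statistics report",
    "========================",
    sprintf("Coupling: BQD %.3f +/- %.3f (n=%d), HC %.3f +/- %.3f (n=%d)",
            group_tab$mean[1], group_tab$sd[1], group_tab$n[1],
            group_tab$mean[2], group_tab$sd[2], group_tab$n[2]),
    sprintf("Pooled t = %.3f, df = %d, p = %.4g", tt$t, tt$df, tt$p),
    sprintf("Adjusted (%s): group estimate %.3f, p = %.4g",
            paste(config$covariates, collapse = ", "), adj$estimate, adj$p),
    sprintf("Bonferroni: alpha = %g, m = %d, threshold = %g",
            config$alpha, m_tests, config$alpha / m_tests),
    "Clinical correlations (BQD arm):",
    sprintf("  %-10s r = %+.4f  n = %d  p = %.4g  significant: %s",
            corr$variable, corr$r, corr$n, corr$p_uncorrected,
            corr$significant_after_correction))
  writeLines(txt, file.path(outdir, "report.txt"))
  log_info("stats report written to %s", outdir)
  invisible(report)
}

#' End-to-end run: simulate, extract, couple, stats
#' @param config a [run_config()].
#' @return the stats report, invisibly.
#' @export
run_all <- function(config) {
  run_simulate(config)
  run_extract(config)
  run_couple(config)
  run_stats(config)
}
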