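# Voxelwise preprocessing and mask-based signal extraction: the two
# branches that turn a 4D volume into the per-subject gBOLD and CSF
# inflow series.

#' Spatial smoothing specification
#' @param fwhm_mm full width at half maximum of the Gaussian kernel in
#'   mm (default 4).  `fwhm_mm = 0` disables smoothing.
#' @return a `smooth_spec` list.
#' @export
smooth_spec <- function(fwhm_mm = 4) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("fwhm_mm must be a nonnegative scalar")
  structure(list(fwhm_mm = fwhm_mm), class = "smooth_spec")
}

#' CSF reference-slice specification
#'
#' The CSF inflow signal is read from a single acquisition slice at
#' the bottom of the imaging volume (junction of lower cerebellum and
#' upper spinal cord), where fresh-spin inflow makes the signal
#' sensitive to fluid flow into the volume.
#'
#' @param slice_index 1-based slice index along the acquisition axis
#'   (default 1 = bottom slice).
#' @param min_voxels minimum number of CSF voxels that must be present
#'   in the slice; fewer triggers a coverage exclusion (default 1).
#' @return a `csf_roi_spec` list.
#' @export
csf_roi_spec <- function(slice_index = 1, min_voxels = 1) {
  if (slice_index < 1 || slice_index != round(slice_index))
    stop("slice_index must be a positive integer")
  if (min_voxels < 1 || min_voxels != round(min_voxels))
    stop("min_voxels must be >= 1")
  structure(list(slice_index = as.integer(slice_index),
                 min_voxels = as.integer(min_voxels)),
            class = "csf_roi_spec")
}

gaussian_axis_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# n x n convolution matrix for a symmetric kernel.  Rows are
# renormalized so the truncated kernel at the grid edge still sums to
# one: constants are preserved everywhere, and total intensity is
# conserved for interior-supported signals (interior columns sum to 1).
axis_conv_matrix <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- max(1L, j - r):min(n, j + r)
    K[i, j] <- w[i - j + r + 1L]
  }
  K / rowSums(K)
}

apply_along_axis1 <- function(arr, K) {
  d <- dim(arr)
  dim(arr) <- c(d[1], prod(d[-1]))
  out <- K %*% arr
  dim(out) <- d
  out
}

#' Gaussian spatial smoothing of a 4D volume
#'
#' Each volume is convolved with a separable Gaussian whose standard
#' deviation per axis is `fwhm / (2 sqrt(2 ln 2))` in mm, converted to
#' voxels via the voxel size.  Kernels are normalized to unit sum, so
#' total intensity is conserved for signals supported away from the
#' grid edge.
#'
#' @param vol a [volume4d()].
#' @param spec a [smooth_spec()]; `fwhm_mm = 0` returns `vol`
#'   unchanged.
#' @return smoothed [volume4d()].
#' @export
smooth_gaussian <- function(vol, spec = smooth_spec()) {
  stopifnot(inherits(vol, "volume4d"), inherits(spec, "smooth_spec"))
  if (spec$fwhm_mm == 0) return(vol)
  sigma_mm <- spec$fwhm_mm / (2 * sqrt(2 * log(2)))
  arr <- vol$data
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    if (n == 1L) next
    K <- axis_conv_matrix(n, gaussian_axis_kernel(sigma_mm / vol$voxel_size[ax]))
    perm <- c(ax, setdiff(1:4, ax))
    arr <- aperm(apply_along_axis1(aperm(arr, perm), K), order(perm))
  }
  volume4d(arr, vol$voxel_size, vol$tr, vol$slice_axis)
}

# Flatten a volume4d to a time-by-voxel matrix.
volume_matrix <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Mask-averaged time series
#'
#' The gBOLD signal is this operation applied with a grey-matter mask:
#' at each time point, the arithmetic mean of the masked voxels.
#'
#' @param vol a [volume4d()].
#' @param mask a [mask_volume()] on the same spatial grid.
#' @return a [time_series()] sampled at the repetition time.
#' @export
extract_mean_series <- function(vol, mask) {
  stopifnot(inherits(vol, "volume4d"), inherits(mask, "mask_volume"))
  if (!identical(dim(mask$data), dim(vol$data)[1:3]))
    stop("mask shape does not match volume spatial shape")
  idx <- which(mask$data)
  if (length(idx) == 0L) stop("empty mask")
  d <- dim(vol$data)
  mat <- matrix(vol$data, nrow = prod(d[1:3]))
  time_series(colMeans(mat[idx, , drop = FALSE]), vol$tr)
}

csf_coverage_error <- function(msg) {
  structure(class = c("csf_coverage_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' CSF inflow series from the reference slice
#'
#' Averages CSF-mask voxels restricted to the designated acquisition
#' slice only.  If fewer than `spec$min_voxels` CSF voxels fall in
#' that slice the scan does not cover the reference region and a
#' `csf_coverage_error` is signalled, mirroring the participant
#' exclusion applied in practice.
#'
#' @param vol a [volume4d()].
#' @param csf_mask a [mask_volume()].
#' @param spec a [csf_roi_spec()].
#' @return a [time_series()].
#' @export
extract_csf_series <- function(vol, csf_mask, spec = csf_roi_spec()) {
  stopifnot(inherits(vol, "volume4d"), inherits(csf_mask, "mask_volume"))
  if (!identical(dim(csf_mask$data), dim(vol$data)[1:3]))
    stop("CSF mask shape does not match volume spatial shape")
  ax <- vol$slice_axis
  if (spec$slice_index > dim(vol$data)[ax])
    stop("slice_index beyond the volume extent")
  slice_sel <- array(FALSE, dim = dim(csf_mask$data))
  idx <- switch(ax,
                `1` = quote(slice_sel[spec$slice_index, , ] <- TRUE),
                `2` = quote(slice_sel[, spec$slice_index, ] <- TRUE),
                `3` = quote(slice_sel[, , spec$slice_index] <- TRUE))
  eval(idx)
  sel <- which(csf_mask$data & slice_sel)
  if (length(sel) < spec$min_voxels)
    stop(csf_coverage_error(sprintf(
      "slice not covered: %d CSF voxel(s) in slice %d, need >= %d",
      length(sel), spec$slice_index, spec$min_voxels)))
  d <- dim(vol$data)
  mat <- matrix(vol$data, nrow = prod(d[1:3]))
  time_series(colMeans(mat[sel, , drop = FALSE]), vol$tr)
}

#' Preprocessing configuration for one subject
#' @param qc a [qc_policy()].
#' @param filter a [filter_spec()].
#' @param smooth a [smooth_spec()].
#' @param csf_roi a [csf_roi_spec()].
#' @param detrend_degree polynomial detrending degree (default 2).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(qc = qc_policy(), filter = filter_spec(),
                            smooth = smooth_spec(), csf_roi = csf_roi_spec(),
                            detrend_degree = 2) {
  structure(list(qc = qc, filter = filter, smooth = smooth, csf_roi = csf_roi,
                 detrend_degree = detrend_degree),
            class = "pipeline_config")
}

#' Full per-subject preprocessing: volume to gBOLD and CSF series
#'
#' gBOLD branch: discard initial volumes, voxelwise polynomial
#' detrend, zero-phase band-pass, Gaussian smoothing, grey-matter mask
#' average, z-score.  CSF branch: identical temporal steps but no
#' smoothing (to avoid diluting the inflow effect across slices),
#' reference-slice CSF average, z-score.  A motion QC failure or a CSF
#' coverage failure yields a flagged record, not an error.
#'
#' @param vol a [volume4d()].
#' @param gm_mask grey-matter [mask_volume()].
#' @param csf_mask CSF [mask_volume()].
#' @param motion a [motion_trace()], or `NULL` to skip motion QC.
#' @param config a [pipeline_config()].
#' @return list with `gbold`, `csf` (z-scored [time_series()] or
#'   `NULL` if excluded), `qc` (motion report), `excluded`,
#'   `exclude_reason` (`"motion"`, `"csf_coverage"` or `NA`).
#' @export
subject_pipeline <- function(vol, gm_mask, csf_mask, motion = NULL,
                             config = pipeline_config()) {
  stopifnot(inherits(vol, "volume4d"), inherits(config, "pipeline_config"))
  qc <- if (!is.null(motion)) motion_qc(motion, config$qc)
        else list(pass = TRUE, max_trans_mm = NA_real_, max_rot_deg = NA_real_)
  if (!qc$pass)
    return(list(gbold = NULL, csf = NULL, qc = qc, excluded = TRUE,
                exclude_reason = "motion"))
  vol <- discard_initial_volumes(vol, config$qc)
  d <- dim(vol$data)
  mat <- volume_matrix(vol)                       # time x voxel
  mat <- detrend_matrix(mat, config$detrend_degree)
  mat <- bandpass_matrix(mat, vol$tr, config$filter)
  filtered <- volume4d(array(t(mat), dim = d), vol$voxel_size, vol$tr,
                       vol$slice_axis)
  smoothed <- smooth_gaussian(filtered, config$smooth)
  gbold <- zscore(extract_mean_series(smoothed, gm_mask))
  csf <- tryCatch(
    zscore(extract_csf_series(filtered, csf_mask, config$csf_roi)),
    csf_coverage_error = function(e) e)
  if (inherits(csf, "csf_coverage_error"))
    return(list(gbold = NULL, csf = NULL, qc = qc, excluded = TRUE,
                exclude_reason = "csf_coverage"))
  list(gbold = gbold, csf = csf, qc = qc, excluded = FALSE,
       exclude_reason = NA_character_)
}
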