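# NIfTI-1 volume/mask I/O, motion-parameter files, and scan-level QC.
#
# No NIfTI reader is available among the package's allowed
# dependencies, so a minimal NIfTI-1 codec is implemented here: the
# fixed 348-byte header plus an uncompressed or gzip voxel block,
# covering the datatypes this pipeline meets (uint8, int16, int32,
# float32, float64).  Orientation metadata beyond voxel size is
# ignored: the pipeline consumes already-registered volumes.

#' 4D fMRI volume
#'
#' @param data 4D numeric array, dimensions (x, y, slice, time); all
#'   spatial dims >= 1 and time dim >= 2.
#' @param voxel_size length-3 positive numeric, mm per axis.
#' @param tr repetition time (seconds per volume), > 0.
#' @param slice_axis spatial axis indexing acquisition slices
#'   (default 3); "bottom slice" means index 1 along this axis.
#' @return object of class `volume4d`.
#' @export
volume4d <- function(data, voxel_size, tr, slice_axis = 3) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("expected 4D array (x, y, slice, time)")
  d <- dim(data)
  if (any(d[1:3] < 1L) || d[4] < 2L)
    stop("spatial dims must be >= 1 and time dim >= 2")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (mm)")
  stop_if_not_scalar_pos(tr, "tr")
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  structure(list(data = data, voxel_size = voxel_size, tr = tr,
                 slice_axis = as.integer(slice_axis)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  cat(sprintf("<volume4d> %s voxels, %d volumes, voxel %s mm, TR %gs\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              paste(format(x$voxel_size), collapse = "x"), x$tr))
  invisible(x)
}

#' 3D mask on the grid of a companion volume
#'
#' @param data 3D array; nonzero voxels are selected.
#' @param voxel_size length-3 positive numeric, mm.
#' @return object of class `mask_volume` with logical `data`.
#' @export
mask_volume <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L) stop("expected 3D mask array")
  sel <- array(data != 0, dim = dim(data))
  if (!any(sel)) stop("empty mask: no selected voxels")
  structure(list(data = sel, voxel_size = as.numeric(voxel_size)),
            class = "mask_volume")
}

nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "numeric", "numeric"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

nifti_connection <- function(path, open) {
  # gzfile transparently reads both plain and gzip streams
  if (open == "rb") gzfile(path, "rb")
  else if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (bitwAnd(sizeof_hdr, -1L) != 1543569408L)  # 348 byte-swapped
      stop(sprintf("not a NIfTI-1 file: %s", path))
  }
  readBin(con, "raw", 36)                                   # unused fields
  dim <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                                   # intent fields
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)     # bitpix
  readBin(con, "raw", 2)                                    # slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  readBin(con, "raw", 348 - 120 - 4)                        # rest of header
  magic <- rawToChar(readBin(con, "raw", 4), multiple = FALSE)
  if (!grepl("^n\\+1", magic)) stop(sprintf("unsupported NIfTI magic in %s", path))
  dt <- nifti_datatypes[nifti_datatypes$code == datatype, ]
  if (nrow(dt) != 1L) stop(sprintf("unsupported NIfTI datatype code %d", datatype))
  ndim <- dim[1]
  shape <- dim[2:(1 + max(ndim, 1L))]
  skip <- round(vox_offset) - 348L  # header consumed through the magic
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop(sprintf("truncated NIfTI data in %s", path))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(as.numeric(vals), dim = shape), ndim = ndim,
       pixdim = pixdim)
}

#' Read a 4D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr repetition time override in seconds; required when the
#'   header time step is missing or non-positive.
#' @param slice_axis acquisition slice axis (default 3).
#' @return a [volume4d()].
#' @export
read_volume <- function(path, tr = NULL, slice_axis = 3) {
  raw <- read_nifti_raw(path)
  if (raw$ndim != 4L)
    stop(sprintf("expected 4D image, got %dD: %s", raw$ndim, path))
  header_tr <- raw$pixdim[5]
  if (is.null(tr)) {
    if (!is.finite(header_tr) || header_tr <= 0)
      stop("non-positive TR in NIfTI header; supply `tr` explicitly")
    tr <- header_tr
  }
  volume4d(raw$data, voxel_size = raw$pixdim[2:4], tr = tr,
           slice_axis = slice_axis)
}

#' Read a 3D NIfTI-1 mask against a reference volume
#'
#' Nonzero voxels become selected.  The mask grid must match the
#' spatial grid of `reference`.
#'
#' @param path path to a `.nii` / `.nii.gz` label or binary image.
#' @param reference the [volume4d()] the mask will be applied to.
#' @return a [mask_volume()].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "volume4d"))
  raw <- read_nifti_raw(path)
  if (raw$ndim != 3L)
    stop(sprintf("expected 3D mask image, got %dD: %s", raw$ndim, path))
  ref_shape <- dim(reference$data)[1:3]
  if (!identical(as.integer(dim(raw$data)), as.integer(ref_shape)))
    stop(sprintf("mask shape (%s) does not match volume spatial shape (%s)",
                 paste(dim(raw$data), collapse = "x"),
                 paste(ref_shape, collapse = "x")))
  if (!any(raw$data != 0)) stop(sprintf("empty mask: %s", path))
  mask_volume(raw$data, voxel_size = reference$voxel_size)
}

write_nifti_header <- function(con, shape, pixdim, datatype, bitpix) {
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  dim8 <- integer(8)
  dim8[1] <- length(shape)
  dim8[2:(1 + length(shape))] <- shape
  dim8[(2 + length(shape)):8] <- 1L
  writeBin(as.integer(dim8), con, size = 2)
  writeBin(raw(14), con)
  writeBin(as.integer(datatype), con, size = 2)
  writeBin(as.integer(bitpix), con, size = 2)
  writeBin(raw(2), con)
  pd8 <- numeric(8)
  pd8[2:(1 + length(pixdim))] <- pixdim
  writeBin(pd8, con, size = 4)
  writeBin(352, con, size = 4)        # vox_offset
  writeBin(c(1, 0), con, size = 4)    # scl_slope, scl_inter
  writeBin(raw(3), con)               # slice_end, slice_code
  writeBin(as.raw(10L), con)          # xyzt_units: mm | sec
  writeBin(raw(348 - 124 - 4), con)
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4), con)               # extension flag
}

#' Write a 4D volume or mask as NIfTI-1
#'
#' Volumes are stored as float32 with TR in `pixdim[4]`; masks as
#' uint8.  Gzip compression is chosen by the `.gz` suffix.
#'
#' @param x a [volume4d()] or [mask_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  if (inherits(x, "volume4d")) {
    write_nifti_header(con, dim(x$data), c(x$voxel_size, x$tr), 16L, 32L)
    writeBin(as.numeric(x$data), con, size = 4)
  } else if (inherits(x, "mask_volume")) {
    write_nifti_header(con, dim(x$data), x$voxel_size, 2L, 8L)
    writeBin(as.integer(x$data), con, size = 1)
  } else stop("can write volume4d or mask_volume objects only")
  invisible(path)
}

#' Per-volume head motion parameters
#'
#' @param translations n-by-3 numeric matrix, mm.
#' @param rotations n-by-3 numeric matrix, degrees.
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L ||
      nrow(translations) != nrow(rotations) || nrow(translations) < 1L)
    stop("translations and rotations must be n x 3 with equal n >= 1")
  if (anyNA(translations) || anyNA(rotations) ||
      any(!is.finite(translations)) || any(!is.finite(rotations)))
    stop("non-finite motion parameters")
  structure(list(translations = translations, rotations = rotations),
            class = "motion_trace")
}

#' Read a 6-column realignment-parameter file
#'
#' Whitespace-delimited text, one row per volume: columns 1-3 are
#' translations (mm), columns 4-6 rotations.  The default `rp-radians`
#' dialect (the SPM/DPABI rp_*.txt convention) stores rotations in
#' radians, which are converted to degrees on read.
#'
#' @param path file path.
#' @param dialect `"rp-radians"` (default) or `"rp-degrees"`.
#' @return a [motion_trace()] with rotations in degrees.
#' @export
read_motion_params <- function(path, dialect = c("rp-radians", "rp-degrees")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- tryCatch(utils::read.table(path, header = FALSE),
                  error = function(e) stop(sprintf(
                    "cannot parse motion file %s: %s", path, conditionMessage(e))))
  if (ncol(tab) != 6L)
    stop(sprintf("motion file %s has %d columns; expected 6", path, ncol(tab)))
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop(sprintf("non-numeric rows in motion file %s", path))
  rot <- unname(as.matrix(tab[, 4:6]))
  if (dialect == "rp-radians") rot <- rot * 180 / pi
  motion_trace(unname(as.matrix(tab[, 1:3])), rot)
}

#' Write a motion trace in rp dialect
#' @param trace a [motion_trace()] (rotations in degrees).
#' @param path output path.
#' @param dialect on-disk rotation unit (default `rp-radians`).
#' @return `path`, invisibly.
#' @export
write_motion_params <- function(trace, path, dialect = c("rp-radians", "rp-degrees")) {
  dialect <- match.arg(dialect)
  rot <- trace$rotations
  if (dialect == "rp-radians") rot <- rot * pi / 180
  utils::write.table(format(cbind(trace$translations, rot), digits = 10),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Scan-level quality-control policy
#'
#' @param n_discard initial volumes to drop (default 10).
#' @param trans_limit_mm maximum allowed absolute translation (default
#'   1.5 mm); values strictly greater fail.
#' @param rot_limit_deg maximum allowed absolute rotation (default
#'   1.5 degrees); strictly greater fails.
#' @return a `qc_policy` list.
#' @export
qc_policy <- function(n_discard = 10, trans_limit_mm = 1.5, rot_limit_deg = 1.5) {
  if (n_discard < 0 || n_discard != round(n_discard)) stop("n_discard must be >= 0")
  stop_if_not_scalar_pos(trans_limit_mm, "trans_limit_mm")
  stop_if_not_scalar_pos(rot_limit_deg, "rot_limit_deg")
  structure(list(n_discard = as.integer(n_discard),
                 trans_limit_mm = trans_limit_mm,
                 rot_limit_deg = rot_limit_deg),
            class = "qc_policy")
}

#' Drop initial volumes
#'
#' Removes the first `policy$n_discard` volumes (signal-equilibration
#' scans); the repetition time is unchanged.
#'
#' @param vol a [volume4d()].
#' @param policy a [qc_policy()].
#' @return a shorter [volume4d()].
#' @export
discard_initial_volumes <- function(vol, policy = qc_policy()) {
  stopifnot(inherits(vol, "volume4d"))
  nd <- policy$n_discard
  nt <- dim(vol$data)[4]
  if (nd >= nt)
    stop(sprintf("cannot discard %d of %d volumes", nd, nt))
  if (nd == 0L) return(vol)
  volume4d(vol$data[, , , (nd + 1L):nt, drop = FALSE], vol$voxel_size,
           vol$tr, vol$slice_axis)
}

#' Head-motion quality control
#'
#' Fails a scan iff the maximum absolute translation exceeds
#' `trans_limit_mm` or the maximum absolute rotation exceeds
#' `rot_limit_deg` (strict inequality, so a value exactly at the limit
#' passes).  Maxima are taken over all volumes and all three axes of
#' the per-volume parameters (displacement relative to the realignment
#' reference), not over frame-to-frame differences.
#'
#' @param trace a [motion_trace()].
#' @param policy a [qc_policy()].
#' @return list with `pass`, `max_trans_mm`, `max_rot_deg`.
#' @export
motion_qc <- function(trace, policy = qc_policy()) {
  stopifnot(inherits(trace, "motion_trace"), inherits(policy, "qc_policy"))
  max_trans <- max(abs(trace$translations))
  max_rot <- max(abs(trace$rotations))
  list(pass = !(max_trans > policy$trans_limit_mm ||
                  max_rot > policy$rot_limit_deg),
       max_trans_mm = max_trans, max_rot_deg = max_rot)
}
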