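#' Focus stack container
#'
#' A `focus_stack` holds a through-focus acquisition: a 3D intensity array
#' together with the calibrated focus position of every plane. The array is
#' indexed `[row, col, plane]`, i.e. `(y, x, z)`; `x` increases with column
#' index, matching camera readout, and plane `k` was acquired at
#' `z_positions_um[k]`. The sign of z is a metadata convention only: every
#' derived metric (sag, depth of field, chromatic offsets) is a difference
#' of z values, so it cancels.
#'
#' @param data 3D numeric array `[row, col, plane]` (a matrix is promoted to
#'   a single-plane stack). Values must be finite and non-negative.
#' @param z_positions_um numeric vector of focus positions in micrometres,
#'   one per plane, strictly monotonic.
#' @param channel free-text channel label (e.g. an emission filter name).
#' @param pixel_size_um lateral pixel pitch in micrometres, or `NA` if
#'   unknown.
#' @param bits integer bit depth of the source container (8 or 16), or `NULL`
#'   when unknown/float. Used to locate the saturation level.
#' @return An object of class `focus_stack`.
#' @seealso [read_stack()], [write_stack()], [build_contrast_map()]
#' @export
focus_stack <- function(data, z_positions_um, channel = "", pixel_size_um = NA_real_,
                        bits = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array [row, col, plane]")
  if (any(!is.finite(data)) || any(data < 0))
    stop("stack intensities must be finite and non-negative")
  z_positions_um <- as.numeric(z_positions_um)
  if (length(z_positions_um) != dim(data)[3L])
    stop("length(z_positions_um) must equal the number of planes")
  if (length(z_positions_um) > 1L) {
    dz <- diff(z_positions_um)
    if (!(all(dz > 0) || all(dz < 0)))
      stop("z_positions_um must be strictly monotonic")
  }
  structure(list(data = data, z_positions_um = z_positions_um,
                 channel = channel, pixel_size_um = pixel_size_um,
                 bits = bits),
            class = "focus_stack")
}

#' @export
print.focus_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<focus_stack> %d x %d px, %d plane(s), z = [%g, %g] um%s\n",
              d[1L], d[2L], d[3L], min(x$z_positions_um), max(x$z_positions_um),
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  invisible(x)
}

#' Calibrated 3D volume container
#'
#' A `qc_volume` is a 3D intensity array `[row, col, plane]` with an
#' anisotropic voxel size, used for bead/PSF volumes and repeated-scan
#' pairs.
#'
#' @param data 3D numeric array `[row, col, plane]`, non-negative.
#' @param voxel_size_um named numeric vector `c(z = , y = , x = )` of voxel
#'   edge lengths in micrometres, all positive.
#' @return An object of class `qc_volume`.
#' @export
qc_volume <- function(data, voxel_size_um = c(z = 1, y = 1, x = 1)) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array [row, col, plane]")
  if (any(!is.finite(data)) || any(data < 0))
    stop("volume intensities must be finite and non-negative")
  v <- voxel_size_um
  if (is.null(names(v)) && length(v) == 3L) names(v) <- c("z", "y", "x")
  if (!all(c("z", "y", "x") %in% names(v)))
    stop("voxel_size_um must be named c(z=, y=, x=)")
  v <- v[c("z", "y", "x")]
  if (any(!is.finite(v)) || any(v <= 0)) stop("all voxel sizes must be > 0")
  structure(list(data = data, voxel_size_um = v), class = "qc_volume")
}

#' @export
print.qc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<qc_volume> %d x %d px, %d plane(s), voxel %g x %g x %g um (z,y,x)\n",
              d[1L], d[2L], d[3L],
              x$voxel_size_um[["z"]], x$voxel_size_um[["y"]], x$voxel_size_um[["x"]]))
  invisible(x)
}

#' Read a multi-page TIFF focus stack
#'
#' Reads a grayscale multi-page TIFF and attaches the z calibration of the
#' focus sweep. TIFF files do not reliably carry focus positions, so the
#' sweep start and step are always supplied by the caller; plane `k` (1-based)
#' is assigned `z_start_um + (k - 1) * z_step_um` in storage order.
#'
#' @param path path to a grayscale multi-page TIFF (8/16-bit integer or
#'   float).
#' @param z_start_um focus position of the first stored plane, micrometres.
#' @param z_step_um focus increment per plane, micrometres; must be finite
#'   and non-zero (negative steps encode a descending sweep).
#' @param channel optional channel label.
#' @param pixel_size_um optional lateral pixel size, micrometres.
#' @return A [focus_stack()]. Integer TIFF data are returned as the original
#'   integer counts.
#' @export
read_stack <- function(path, z_start_um, z_step_um, channel = "",
                       pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.finite(z_step_um) || z_step_um == 0)
    stop("z_step_um must be finite and non-zero")
  arr <- .read_tiff_array(path)
  n <- dim(arr$data)[3L]
  z <- z_start_um + (seq_len(n) - 1) * z_step_um
  focus_stack(arr$data, z, channel = channel, pixel_size_um = pixel_size_um,
              bits = arr$bits)
}

#' Read a multi-page TIFF as a calibrated volume
#'
#' @inheritParams read_stack
#' @param voxel_size_um named `c(z=, y=, x=)` voxel size in micrometres.
#' @return A [qc_volume()].
#' @export
read_volume <- function(path, voxel_size_um = c(z = 1, y = 1, x = 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- .read_tiff_array(path)
  qc_volume(arr$data, voxel_size_um)
}

.read_tiff_array <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("TIFF has no pages: ", path)
  bps <- attr(pages[[1L]], "bits.per.sample")
  if (!is.null(bps) && bps %in% c(8L, 16L)) {
    # integer samples: re-read unscaled so raw counts roundtrip exactly
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("non-uniform plane dimensions in ", path)
  bits <- attr(pages[[1L]], "bits.per.sample")
  integer_data <- is.integer(pages[[1L]])
  data <- array(0, c(dims[1L, 1L], dims[2L, 1L], length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]]
  list(data = data, bits = if (integer_data && !is.null(bits)) as.integer(bits) else NULL)
}

#' Write a stack or volume as a multi-page grayscale TIFF
#'
#' Integer-valued data are stored losslessly as 8- or 16-bit samples
#' (whichever fits); floating-point data are stored as 32-bit float samples
#' and must already lie in the normalized intensity range \[0, 1\], the
#' convention of R image packages. Raw camera counts should be written as
#' integers.
#'
#' @param stack a [focus_stack()], [qc_volume()], or plain 3D array.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  data <- if (is.list(stack)) stack$data else stack
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L || length(data) == 0L)
    stop("'stack' must contain a non-empty 3D array")
  if (any(!is.finite(data))) stop("cannot write non-finite intensities")
  integerish <- all(data == round(data))
  pages <- lapply(seq_len(dim(data)[3L]), function(k) data[, , k, drop = TRUE])
  if (integerish) {
    mx <- max(data)
    if (min(data) < 0) stop("negative intensities cannot be written")
    bits <- if (mx <= 255) 8L else 16L
    if (mx > 65535) stop("integer data exceed 16-bit range; rescale first")
    scale <- 2^bits - 1
    ok <- tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                          bits.per.sample = bits, compression = "none")
  } else {
    if (max(data) > 1 || min(data) < 0)
      stop("float data must lie in [0, 1]; quantize to integer counts instead")
    ok <- tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                          compression = "none")
  }
  if (identical(ok, FALSE)) stop("failed to write ", path)
  invisible(path)
}

#' Write an analysis report to JSON or CSV
#'
#' JSON output carries the full nested report, including metadata such as
#' grid geometry, z positions, the package version and any seed recorded in
#' the report; `NaN`/`NA` entries become JSON `null`. CSV output carries the
#' report's flat per-item table (per subregion, per bead, or per candidate);
#' `NaN` entries become empty cells.
#'
#' @param report a report object (e.g. the result of [analyze_flatness()],
#'   [measure_psf()], [validate_scan_pair()], or [chromatic_focal_offset()]),
#'   or any list of scalars/arrays.
#' @param path output file path.
#' @param fmt `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, fmt = c("json", "csv")) {
  fmt <- tryCatch(match.arg(fmt), error = function(e)
    stop("unsupported fmt; use 'json' or 'csv'"))
  if (fmt == "json") {
    payload <- report_list(report)
    payload$software <- list(package = "mesoqc",
                             version = as.character(utils::packageVersion("mesoqc")))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    tab <- report_table(report)
    utils::write.csv(tab, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Nested-list form of a report (JSON payload)
#'
#' @param report a report object.
#' @return A plain list of scalars, vectors and matrices.
#' @export
report_list <- function(report) UseMethod("report_list")

#' @export
report_list.default <- function(report) {
  if (!is.list(report)) stop("cannot serialize report of class ",
                             paste(class(report), collapse = "/"))
  unclass(report)
}

#' Flat per-item table of a report (CSV payload)
#'
#' @param report a report object.
#' @return A data.frame with one row per item (subregion, bead, candidate).
#' @export
report_table <- function(report) UseMethod("report_table")

#' @export
report_table.default <- function(report) {
  if (is.data.frame(report)) return(report)
  stop("no tabular form defined for class ", paste(class(report), collapse = "/"))
}
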