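# System-resolution measurement from sub-resolution bead volumes: detect
# bead centers, drop clusters, fit Gaussians laterally and axially, convert
# to FWHM and summarize across the field.

#' Convert a Gaussian sigma to FWHM
#'
#' `FWHM = 2 * sqrt(2 * log(2)) * sigma ~= 2.35482 * sigma`.
#'
#' @param sigma positive Gaussian standard deviation (any length unit).
#' @return FWHM in the same unit.
#' @export
sigma_to_fwhm <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  2 * sqrt(2 * log(2)) * sigma
}

#' Detect bead candidates in a volume
#'
#' Finds local maxima (26-neighborhood) exceeding
#' `background + min_snr * noise_sd`, where the background is the global
#' median intensity and the noise scale is the median absolute deviation
#' (scaled to the Gaussian sigma). Robust global statistics are adequate
#' because beads are sparse and the background of a calibration volume is
#' flat.
#'
#' @param volume a [qc_volume()] with at least 3 planes.
#' @param min_snr detection threshold in noise sigmas above background.
#' @param min_intensity additional absolute intensity floor.
#' @return A data.frame of candidates: integer seed `z_vox`, `y_vox`,
#'   `x_vox` (1-based), micrometre center estimates `z_um`, `y_um`, `x_um`
#'   (voxel centers), `peak_intensity`, `local_background`, `noise_sd`.
#' @export
detect_bead_candidates <- function(volume, min_snr = 8, min_intensity = 0) {
  stopifnot(inherits(volume, "qc_volume"))
  v <- volume$data
  if (length(v) == 0L) stop("empty volume")
  if (dim(v)[3L] < 3L) stop("volume must have at least 3 planes")
  bg <- stats::median(v)
  noise <- stats::mad(v)   # 1.4826 * MAD
  thr <- max(bg + min_snr * noise, min_intensity)
  idx <- which(v > thr, arr.ind = TRUE)   # columns: row (y), col (x), plane (z)
  keep <- logical(nrow(idx))
  d <- dim(v)
  if (nrow(idx) > 0) for (n in seq_len(nrow(idx))) {
    y <- idx[n, 1L]; x <- idx[n, 2L]; z <- idx[n, 3L]
    if (y == 1L || x == 1L || z == 1L || y == d[1L] || x == d[2L] || z == d[3L]) next
    nb <- v[(y - 1L):(y + 1L), (x - 1L):(x + 1L), (z - 1L):(z + 1L)]
    if (v[y, x, z] == max(nb) && sum(nb == v[y, x, z]) == 1L) keep[n] <- TRUE
  }
  idx <- idx[keep, , drop = FALSE]
  vs <- volume$voxel_size_um
  n <- nrow(idx)
  data.frame(
    z_vox = idx[, 3L], y_vox = idx[, 1L], x_vox = idx[, 2L],
    z_um = (idx[, 3L] - 0.5) * vs[["z"]],
    y_um = (idx[, 1L] - 0.5) * vs[["y"]],
    x_um = (idx[, 2L] - 0.5) * vs[["x"]],
    peak_intensity = if (n) v[idx] else numeric(0),
    local_background = rep(bg, n), noise_sd = rep(noise, n))
}

#' Exclude clustered bead candidates
#'
#' Overlapping bead images bias Gaussian fits, so any candidate with a
#' neighbour closer than `min_separation_um` is removed -- both members of
#' a close pair are dropped. Order is preserved.
#'
#' @param candidates data.frame from [detect_bead_candidates()] (needs
#'   `z_um`, `y_um`, `x_um`).
#' @param min_separation_um exclusion radius in micrometres (>= 0).
#' @return The kept subset of `candidates`, with attribute `"dropped"`
#'   giving the row indices removed.
#' @export
filter_bead_clusters <- function(candidates, min_separation_um = 5) {
  if (min_separation_um < 0) stop("min_separation_um must be >= 0")
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  p <- as.matrix(candidates[, c("z_um", "y_um", "x_um")])
  dd <- as.matrix(stats::dist(p))
  diag(dd) <- Inf
  close <- apply(dd < min_separation_um, 1L, any)
  out <- candidates[!close, , drop = FALSE]
  attr(out, "dropped") <- which(close)
  out
}

#' Fit a 3D bead image with Gaussians
#'
#' Extracts a window around the candidate, picks the bead's best plane
#' (maximum windowed intensity after a 3-point moving average along z),
#' fits a 2D elliptical Gaussian plus constant background there for the
#' lateral widths, then fits a 1D Gaussian along z through the refined
#' center for the axial width. Fitting is invariant under intensity gain
#' and offset. Beads whose window clips the volume get status `"edge"` and
#' no widths; fits with `r_squared < r2_min` or widths at the bounds get
#' status `"poor_fit"`.
#'
#' @param volume a [qc_volume()].
#' @param candidate one-row data.frame (a row of
#'   [detect_bead_candidates()] output).
#' @param window_halfwidth_vox named `c(z=, y=, x=)` half-widths of the fit
#'   window in voxels.
#' @param r2_min minimum coefficient of determination for an `"ok"` fit.
#' @return A one-row data.frame (`bead_fit`): micrometre center, sigmas,
#'   `fwhm_x_um`, `fwhm_y_um`, `fwhm_lateral_um` (geometric mean of x/y),
#'   `fwhm_z_um`, `amplitude`, `background`, `r_squared` and `status`.
#' @export
fit_bead_gaussian <- function(volume, candidate,
                              window_halfwidth_vox = c(z = 6, y = 5, x = 5),
                              r2_min = 0.8) {
  stopifnot(inherits(volume, "qc_volume"))
  v <- volume$data
  vs <- volume$voxel_size_um
  w <- window_halfwidth_vox[c("z", "y", "x")]
  cz <- candidate$z_vox; cy <- candidate$y_vox; cx <- candidate$x_vox
  blank <- data.frame(z_um = NA_real_, y_um = NA_real_, x_um = NA_real_,
                      sigma_x_um = NA_real_, sigma_y_um = NA_real_,
                      sigma_z_um = NA_real_, fwhm_x_um = NA_real_,
                      fwhm_y_um = NA_real_, fwhm_lateral_um = NA_real_,
                      fwhm_z_um = NA_real_, amplitude = NA_real_,
                      background = NA_real_, r_squared = NA_real_,
                      status = "edge", stringsAsFactors = FALSE)
  if (cz - w[["z"]] < 1 || cz + w[["z"]] > dim(v)[3L] ||
      cy - w[["y"]] < 1 || cy + w[["y"]] > dim(v)[1L] ||
      cx - w[["x"]] < 1 || cx + w[["x"]] > dim(v)[2L]) return(blank)
  zr <- (cz - w[["z"]]):(cz + w[["z"]])
  yr <- (cy - w[["y"]]):(cy + w[["y"]])
  xr <- (cx - w[["x"]]):(cx + w[["x"]])
  win <- v[yr, xr, zr]
  # best plane: z-profile of windowed sums, 3-point smoothed
  zprof <- apply(win, 3L, sum)
  zs <- stats::filter(zprof, rep(1 / 3, 3L))
  zs[c(1L, length(zs))] <- zprof[c(1L, length(zprof))]
  kbest <- which.max(zs)
  plane <- win[, , kbest]
  df2 <- data.frame(i = as.vector(row(plane)), j = as.vector(col(plane)),
                    val = as.vector(plane))
  mx <- max(plane); mn <- min(plane)
  pk <- which(plane == mx, arr.ind = TRUE)[1L, ]
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      val ~ b + A * exp(-((i - y0)^2 / (2 * sy^2) + (j - x0)^2 / (2 * sx^2))),
      data = df2,
      start = list(b = mn, A = mx - mn, y0 = pk[[1L]], x0 = pk[[2L]],
                   sy = 1.5, sx = 1.5),
      lower = c(-Inf, 0, 1, 1, 0.2, 0.2),
      upper = c(Inf, Inf, nrow(plane), ncol(plane),
                nrow(plane), ncol(plane)),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  poor <- function(status = "poor_fit") { b <- blank; b$status <- status; b }
  if (is.null(fit2)) return(poor())
  p2 <- stats::coef(fit2)
  r2_2d <- 1 - sum(stats::residuals(fit2)^2) / sum((df2$val - mean(df2$val))^2)
  # axial profile through the refined lateral center
  yi <- min(max(round(p2[["y0"]]), 1L), length(yr))
  xi <- min(max(round(p2[["x0"]]), 1L), length(xr))
  zprof2 <- win[yi, xi, ]
  dfz <- data.frame(k = seq_along(zprof2), val = zprof2)
  fitz <- tryCatch(
    minpack.lm::nlsLM(
      val ~ b + A * exp(-(k - z0)^2 / (2 * sz^2)), data = dfz,
      start = list(b = min(zprof2), A = max(zprof2) - min(zprof2),
                   z0 = which.max(zprof2), sz = 1.5),
      lower = c(-Inf, 0, 1, 0.2), upper = c(Inf, Inf, length(zprof2), length(zprof2)),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fitz)) return(poor())
  pz <- stats::coef(fitz)
  r2_z <- 1 - sum(stats::residuals(fitz)^2) / sum((dfz$val - mean(dfz$val))^2)
  r2 <- min(r2_2d, r2_z)
  sx_v <- p2[["sx"]]; sy_v <- p2[["sy"]]; sz_v <- pz[["sz"]]
  at_bounds <- sx_v <= 0.2 + 1e-9 || sy_v <= 0.2 + 1e-9 || sz_v <= 0.2 + 1e-9 ||
    sx_v >= ncol(plane) - 1e-9 || sy_v >= nrow(plane) - 1e-9 ||
    sz_v >= length(zprof2) - 1e-9
  status <- if (!is.finite(r2) || r2 < r2_min || at_bounds) "poor_fit" else "ok"
  if (status == "poor_fit") return(poor())
  sig_um <- c(x = sx_v * vs[["x"]], y = sy_v * vs[["y"]], z = sz_v * vs[["z"]])
  fw <- sigma_to_fwhm(sig_um)
  data.frame(
    z_um = (zr[1L] - 1 + pz[["z0"]] - 0.5) * vs[["z"]],
    y_um = (yr[1L] - 1 + p2[["y0"]] - 0.5) * vs[["y"]],
    x_um = (xr[1L] - 1 + p2[["x0"]] - 0.5) * vs[["x"]],
    sigma_x_um = sig_um[["x"]], sigma_y_um = sig_um[["y"]],
    sigma_z_um = sig_um[["z"]],
    fwhm_x_um = fw[["x"]], fwhm_y_um = fw[["y"]],
    fwhm_lateral_um = sqrt(fw[["x"]] * fw[["y"]]),
    fwhm_z_um = fw[["z"]],
    amplitude = p2[["A"]], background = p2[["b"]], r_squared = r2,
    status = "ok", stringsAsFactors = FALSE)
}

#' Summarize bead fits into a PSF report
#'
#' @param fits data.frame of bead fits (rows from [fit_bead_gaussian()]).
#' @param n_detected number of candidates before filtering (for
#'   bookkeeping; defaults to `nrow(fits)`).
#' @param hist_binwidth_um histogram bin width in micrometres.
#' @return A `psf_report`: list with `fits`, `n_detected`, `n_kept`
#'   (status `"ok"`), `lateral_um` and `axial_um` summaries (`mean`, `sd`,
#'   `hist`), computed over ok fits only. `sd` is the sample standard
#'   deviation (0 for a single fit).
#' @export
summarize_psf <- function(fits, n_detected = nrow(fits), hist_binwidth_um = 0.25) {
  ok <- fits[fits$status == "ok", , drop = FALSE]
  if (nrow(ok) < 1L) stop("no fits with status 'ok'")
  summ <- function(x) {
    br <- seq(0, max(x) + hist_binwidth_um, by = hist_binwidth_um)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
         n = length(x),
         hist = list(mids = h$mids, counts = h$counts))
  }
  structure(list(fits = fits, n_detected = n_detected, n_kept = nrow(ok),
                 lateral_um = summ(ok$fwhm_lateral_um),
                 axial_um = summ(ok$fwhm_z_um)),
            class = "psf_report")
}

#' Measure the PSF from a bead volume
#'
#' One-call pipeline: detect candidates, exclude clusters and edge beads,
#' fit every kept bead, and summarize lateral and axial FWHM across the
#' field.
#'
#' @param volume a [qc_volume()] of sparse sub-resolution beads.
#' @param min_snr detection threshold, see [detect_bead_candidates()].
#' @param min_separation_um cluster-exclusion radius, see
#'   [filter_bead_clusters()].
#' @param window_halfwidth_vox fit window half-widths, see
#'   [fit_bead_gaussian()].
#' @param r2_min goodness-of-fit cut.
#' @return A `psf_report` (see [summarize_psf()]); `fits` carries one row
#'   per non-cluster candidate with its status, and micrometre positions
#'   for field maps. Has `print` and `plot` methods.
#' @export
measure_psf <- function(volume, min_snr = 8, min_separation_um = 5,
                        window_halfwidth_vox = c(z = 6, y = 5, x = 5),
                        r2_min = 0.8) {
  cands <- detect_bead_candidates(volume, min_snr = min_snr)
  kept <- filter_bead_clusters(cands, min_separation_um)
  if (nrow(kept) < 1L) stop("no isolated bead candidates detected")
  fits <- do.call(rbind, lapply(seq_len(nrow(kept)), function(n)
    fit_bead_gaussian(volume, kept[n, , drop = FALSE],
                      window_halfwidth_vox = window_halfwidth_vox,
                      r2_min = r2_min)))
  summarize_psf(fits, n_detected = nrow(cands))
}

#' @export
print.psf_report <- function(x, ...) {
  cat("<psf_report>\n")
  cat(sprintf("  beads: %d detected, %d fitted ok\n", x$n_detected, x$n_kept))
  cat(sprintf("  lateral FWHM : %.3f +/- %.3f um (n = %d)\n",
              x$lateral_um$mean, x$lateral_um$sd, x$lateral_um$n))
  cat(sprintf("  axial FWHM   : %.3f +/- %.3f um (n = %d)\n",
              x$axial_um$mean, x$axial_um$sd, x$axial_um$n))
  invisible(x)
}

#' @export
summary.psf_report <- function(object, ...) {
  print(object)
  invisible(list(lateral_um = object$lateral_um[c("mean", "sd", "n")],
                 axial_um = object$axial_um[c("mean", "sd", "n")]))
}

#' @export
plot.psf_report <- function(x, which = c("lateral_map", "axial_map",
                                         "lateral_hist", "axial_hist"), ...) {
  which <- match.arg(which)
  ok <- x$fits[x$fits$status == "ok", , drop = FALSE]
  if (which %in% c("lateral_map", "axial_map")) {
    val <- if (which == "lateral_map") ok$fwhm_lateral_um else ok$fwhm_z_um
    pal <- grDevices::hcl.colors(64, "viridis")
    col <- pal[cut(val, 64, labels = FALSE)]
    graphics::plot(ok$x_um, ok$y_um, col = col, pch = 16,
                   xlab = "x (um)", ylab = "y (um)",
                   main = if (which == "lateral_map")
                     "Lateral FWHM across field (um)" else
                       "Axial FWHM across field (um)", ...)
  } else {
    s <- if (which == "lateral_hist") x$lateral_um else x$axial_um
    graphics::barplot(s$hist$counts, names.arg = round(s$hist$mids, 2),
                      xlab = "FWHM (um)", ylab = "beads",
                      main = sprintf("mean %.2f um, sd %.2f um", s$mean, s$sd),
                      ...)
  }
  invisible(x)
}

#' @export
report_list.psf_report <- function(report) {
  list(n_detected = report$n_detected, n_kept = report$n_kept,
       lateral_um = report$lateral_um, axial_um = report$axial_um,
       fits = report$fits)
}

#' @export
report_table.psf_report <- function(report) report$fits
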