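# Objective contrast and field-flatness analysis from Ronchi-target focus
# stacks: percentile contrast on a subregion grid, 3D contrast map,
# best-focus surface, tilt-compensated sag, depth of field, uniformity and
# chromatic focal offsets.

#' Partition a frame into a subregion grid
#'
#' Splits a `width_px` x `height_px` frame into `nx_sub` x `ny_sub`
#' near-equal rectangular subregions. Boundary `i` (0-based pixel
#' coordinate) sits at `floor(i * width / nx_sub)`, so subregion sizes
#' differ by at most one pixel and the grid covers the frame exactly with
#' half-open `[a, b)` pixel intervals.
#'
#' @param width_px,height_px frame size in pixels.
#' @param nx_sub,ny_sub subregion counts along x (columns) and y (rows);
#'   defaults 32 x 20.
#' @return A `subregion_grid` with boundary vectors `col_bounds`,
#'   `row_bounds` (length `nx_sub + 1` / `ny_sub + 1`, 0-based pixel
#'   boundaries) and subregion center coordinates `centers_x_px`,
#'   `centers_y_px` plus normalized field coordinates `centers_x_norm`,
#'   `centers_y_norm` in \[-1, 1\].
#' @export
partition_grid <- function(width_px, height_px, nx_sub = 32, ny_sub = 20) {
  if (nx_sub < 1 || ny_sub < 1) stop("subregion counts must be >= 1")
  if (nx_sub > width_px || ny_sub > height_px)
    stop("more subregions than pixels")
  col_bounds <- floor((0:nx_sub) * width_px / nx_sub)
  row_bounds <- floor((0:ny_sub) * height_px / ny_sub)
  cx <- (col_bounds[-1] + col_bounds[-(nx_sub + 1)]) / 2
  cy <- (row_bounds[-1] + row_bounds[-(ny_sub + 1)]) / 2
  structure(list(nx_sub = nx_sub, ny_sub = ny_sub,
                 col_bounds = col_bounds, row_bounds = row_bounds,
                 centers_x_px = cx, centers_y_px = cy,
                 centers_x_norm = (cx - width_px / 2) / (width_px / 2),
                 centers_y_norm = (cy - height_px / 2) / (height_px / 2),
                 width_px = width_px, height_px = height_px),
            class = "subregion_grid")
}

#' @export
print.subregion_grid <- function(x, ...) {
  cat(sprintf("<subregion_grid> %d x %d subregions over %d x %d px\n",
              x$nx_sub, x$ny_sub, x$width_px, x$height_px))
  invisible(x)
}

#' Percentile contrast of a set of intensities
#'
#' Robust Michelson-type contrast of a subregion,
#' `C = (P99 - P1) / (P99 + P1)`, with the 1st and 99th percentiles standing
#' in for min and max to reject noise and hot/dead pixels. Percentiles use
#' the sorted-order linear-interpolation convention
#' (rank `1 + q/100 * (n - 1)`, [stats::quantile()] type 7).
#'
#' @param values numeric vector of at least 2 finite, non-negative
#'   intensities.
#' @return Contrast in \[0, 1\]; `NaN` when `P99 + P1 == 0` (no signal).
#' @export
subregion_contrast <- function(values) {
  if (length(values) < 2L) stop("need at least 2 intensity values")
  if (any(!is.finite(values))) stop("intensities must be finite")
  if (any(values < 0)) stop("intensities must be non-negative")
  p <- stats::quantile(values, c(0.01, 0.99), names = FALSE, type = 7)
  if (p[1L] + p[2L] == 0) return(NaN)
  (p[2L] - p[1L]) / (p[2L] + p[1L])
}

#' Build the 3D contrast map of a focus stack
#'
#' Applies [subregion_contrast()] to every subregion of every plane,
#' producing `C(x, y, z)`: a percentile estimate of the modulation transfer
#' function at the grating frequency across the field and through focus.
#' Subregions in which more than `saturation_fraction` of pixels sit at the
#' container maximum are flagged `NaN` for that plane (the 99th percentile
#' is meaningless under clipping).
#'
#' @param stack a [focus_stack()].
#' @param grid a [subregion_grid()] matching the stack frame size; default
#'   32 x 20.
#' @param saturation_level intensity treated as clipped; defaults to
#'   `2^bits - 1` when the stack records an integer bit depth, otherwise no
#'   saturation check.
#' @param saturation_fraction tolerated fraction of saturated pixels
#'   (default 0.01).
#' @return A `contrast_map`: list with `values` (array
#'   `[ny_sub, nx_sub, n_planes]` in \[0, 1\], `NaN` where flagged),
#'   `z_positions_um`, `grid`, `channel`.
#' @export
build_contrast_map <- function(stack, grid = NULL, saturation_level = NULL,
                               saturation_fraction = 0.01) {
  stopifnot(inherits(stack, "focus_stack"))
  d <- dim(stack$data)
  if (is.null(grid)) grid <- partition_grid(d[2L], d[1L])
  if (grid$width_px != d[2L] || grid$height_px != d[1L])
    stop("grid frame size does not match stack")
  if (is.null(saturation_level) && !is.null(stack$bits))
    saturation_level <- 2^stack$bits - 1
  nz <- d[3L]
  vals <- array(NA_real_, c(grid$ny_sub, grid$nx_sub, nz))
  rb <- grid$row_bounds; cb <- grid$col_bounds
  for (k in seq_len(nz)) {
    plane <- stack$data[, , k]
    for (j in seq_len(grid$ny_sub)) {
      rows <- (rb[j] + 1L):rb[j + 1L]
      for (i in seq_len(grid$nx_sub)) {
        block <- plane[rows, (cb[i] + 1L):cb[i + 1L]]
        if (!is.null(saturation_level) &&
            mean(block >= saturation_level) > saturation_fraction) {
          vals[j, i, k] <- NaN
        } else {
          vals[j, i, k] <- subregion_contrast(block)
        }
      }
    }
  }
  structure(list(values = vals, z_positions_um = stack$z_positions_um,
                 grid = grid, channel = stack$channel),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> %d x %d subregions, %d plane(s), contrast %.3f-%.3f\n",
              x$grid$ny_sub, x$grid$nx_sub, dim(x$values)[3L],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Maximum-contrast map
#'
#' Elementwise maximum of the contrast map along z. Because the maximum of
#' the through-focus contrast curve does not depend on where the peak sits,
#' this map is invariant to the tip/tilt of the test target and can be used
#' to cross-compare objectives.
#'
#' @param cmap a `contrast_map` from [build_contrast_map()].
#' @return Matrix `[ny_sub, nx_sub]` of peak contrast; `NaN` only where all
#'   planes are flagged (an error if any subregion has no valid plane).
#' @export
max_contrast_map <- function(cmap) {
  stopifnot(inherits(cmap, "contrast_map"))
  if (dim(cmap$values)[3L] < 1L) stop("contrast map has no planes")
  m <- apply(cmap$values, c(1L, 2L), function(v)
    if (all(is.na(v))) NaN else max(v, na.rm = TRUE))
  if (any(is.na(m))) stop("subregion(s) with no valid plane in any z")
  m
}

#' Best-focus surface from a contrast map
#'
#' For every subregion, locates the peak of contrast vs focus position.
#' The default refines the discrete argmax by fitting a parabola through
#' the peak sample and its two neighbours (exact for a locally quadratic
#' peak); `"gaussian"` fits a full Gaussian-plus-offset profile;
#' `"argmax"` returns the sampled grid position. Subregions whose peak sits
#' at the sweep boundary (peak possibly outside the sweep) or that are all
#' `NaN` are masked invalid.
#'
#' @param cmap a `contrast_map`.
#' @param refine `"parabolic"` (default), `"argmax"` or `"gaussian"`.
#' @return A `best_focus_surface`: list with `z0_um` (matrix
#'   `[ny_sub, nx_sub]`, `NA` where invalid), `peak_contrast`, `valid_mask`,
#'   `grid`, `z_positions_um`, `channel`.
#' @export
best_focus_surface <- function(cmap, refine = c("parabolic", "argmax", "gaussian")) {
  stopifnot(inherits(cmap, "contrast_map"))
  refine <- match.arg(refine)
  z <- cmap$z_positions_um
  nz <- length(z)
  if (refine != "argmax" && nz < 3L)
    stop("sub-step refinement needs at least 3 planes")
  ny <- dim(cmap$values)[1L]; nx <- dim(cmap$values)[2L]
  z0 <- matrix(NA_real_, ny, nx)
  pk <- matrix(NA_real_, ny, nx)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    prof <- cmap$values[j, i, ]
    ok <- which(!is.na(prof))
    if (length(ok) < if (refine == "argmax") 1L else 3L) next
    kk <- ok[which.max(prof[ok])]
    # boundary peak: true best focus may lie outside the sweep
    if (kk == ok[1L] || kk == ok[length(ok)]) next
    pos <- match(kk, ok)
    k0 <- ok[pos - 1L]; k2 <- ok[pos + 1L]
    if (refine == "argmax") {
      z0[j, i] <- z[kk]; pk[j, i] <- prof[kk]
    } else if (refine == "parabolic") {
      fit <- .parabolic_vertex(z[c(k0, kk, k2)], prof[c(k0, kk, k2)])
      z0[j, i] <- fit[1L]; pk[j, i] <- fit[2L]
    } else {
      fit <- .gaussian_peak_1d(z[ok], prof[ok], z[kk], prof[kk])
      if (is.null(fit)) { z0[j, i] <- z[kk]; pk[j, i] <- prof[kk] }
      else { z0[j, i] <- fit[1L]; pk[j, i] <- fit[2L] }
    }
  }
  if (!any(is.finite(z0))) stop("no valid subregion peaks found")
  structure(list(z0_um = z0, peak_contrast = pk, valid_mask = is.finite(z0),
                 grid = cmap$grid, z_positions_um = z,
                 channel = cmap$channel),
            class = "best_focus_surface")
}

# vertex (location, value) of the parabola through three points
.parabolic_vertex <- function(x, y) {
  cf <- solve(cbind(1, x, x^2), y)       # y = c + b*x + a*x^2
  a <- cf[3L]; b <- cf[2L]; c0 <- cf[1L]
  if (a >= 0) return(c(x[2L], y[2L]))    # not concave; keep the sample
  xv <- -b / (2 * a)
  xv <- min(max(xv, x[1L]), x[3L])       # clamp within the bracket
  c(xv, c0 + b * xv + a * xv^2)
}

.gaussian_peak_1d <- function(z, c_val, z_guess, c_guess) {
  df <- data.frame(z = z, c = c_val)
  fit <- tryCatch(
    minpack.lm::nlsLM(c ~ b + A * exp(-(z - z0)^2 / (2 * w^2)), data = df,
                      start = list(b = min(c_val), A = c_guess - min(c_val),
                                   z0 = z_guess, w = diff(range(z)) / 6),
                      lower = c(-Inf, 0, min(z), 1e-6),
                      upper = c(Inf, Inf, max(z), diff(range(z)) * 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  c(p[["z0"]], p[["b"]] + p[["A"]])
}

#' Least-squares tilt plane of a best-focus surface
#'
#' Fits `z0 = a0 + ax * x + ay * y` over valid subregions, with `x`, `y`
#' the subregion centers in normalized field units (\[-1, 1\] across the
#' frame). The fitted plane captures the residual tip/tilt of the test
#' target, which is not a property of the objective and is removed before
#' the sag is measured.
#'
#' @param surface a `best_focus_surface`.
#' @return Named numeric `c(a0, ax, ay)` in micrometres (per normalized
#'   field unit for the slopes).
#' @export
fit_tilt_plane <- function(surface) {
  stopifnot(inherits(surface, "best_focus_surface"))
  g <- surface$grid
  xn <- matrix(g$centers_x_norm, g$ny_sub, g$nx_sub, byrow = TRUE)
  yn <- matrix(g$centers_y_norm, g$ny_sub, g$nx_sub)
  ok <- surface$valid_mask
  if (sum(ok) < 3L) stop("need at least 3 valid subregions")
  X <- cbind(1, xn[ok], yn[ok])
  if (qr(X)$rank < 3L) stop("subregion geometry is rank-deficient (collinear)")
  cf <- stats::lm.fit(X, surface$z0_um[ok])$coefficients
  stats::setNames(as.numeric(cf), c("a0", "ax", "ay"))
}

#' Tilt-corrected field flatness of a best-focus surface
#'
#' Removes the least-squares tilt plane from the best-focus surface and
#' reports the sag: the peak-to-valley of the detrended surface over valid
#' subregions, the field-flatness figure of merit. A robust variant (span
#' between the 2nd and 98th percentiles of the detrended surface) is also
#' reported to resist outlier subregions.
#'
#' @param surface a `best_focus_surface`.
#' @return A list with `plane_fit` (`c(a0, ax, ay)`), `detrended_z0`
#'   (matrix, `NA` where invalid), `sag_um` (peak-to-valley) and
#'   `sag_robust_um` (2-98 percentile span).
#' @export
field_flatness <- function(surface) {
  pf <- fit_tilt_plane(surface)
  g <- surface$grid
  xn <- matrix(g$centers_x_norm, g$ny_sub, g$nx_sub, byrow = TRUE)
  yn <- matrix(g$centers_y_norm, g$ny_sub, g$nx_sub)
  det <- surface$z0_um - (pf[["a0"]] + pf[["ax"]] * xn + pf[["ay"]] * yn)
  v <- det[surface$valid_mask]
  list(plane_fit = pf, detrended_z0 = det,
       sag_um = diff(range(v)),
       sag_robust_um = diff(stats::quantile(v, c(0.02, 0.98), names = FALSE)))
}

#' Depth-of-field map
#'
#' Per subregion, the z-extent over which contrast stays at or above
#' `rel_threshold` times the local peak contrast, with the crossing points
#' linearly interpolated between focus samples. For a Gaussian
#' contrast-vs-defocus curve of half-width `w` and the default threshold
#' 0.5 this is the full width at half maximum, `2 * w * sqrt(2 * log(2))`.
#' Subregions whose profile does not fall below the threshold within the
#' sweep on both sides (peak at or beyond the boundary) are flagged `NaN`.
#'
#' @param cmap a `contrast_map`.
#' @param rel_threshold relative threshold in (0, 1\]; default 0.5.
#' @return Matrix `[ny_sub, nx_sub]` of depth of field in micrometres.
#' @export
depth_of_field_map <- function(cmap, rel_threshold = 0.5) {
  stopifnot(inherits(cmap, "contrast_map"))
  if (rel_threshold <= 0 || rel_threshold > 1)
    stop("rel_threshold must be in (0, 1]")
  z <- cmap$z_positions_um
  ny <- dim(cmap$values)[1L]; nx <- dim(cmap$values)[2L]
  out <- matrix(NaN, ny, nx)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    prof <- cmap$values[j, i, ]
    ok <- !is.na(prof)
    if (sum(ok) < 3L) next
    zz <- z[ok]; cc <- prof[ok]
    kk <- which.max(cc)
    thr <- rel_threshold * cc[kk]
    if (cc[kk] <= 0) next
    # walk outwards from the peak to the first crossings
    lo <- NA_real_; hi <- NA_real_
    for (k in kk:1) if (cc[k] < thr) {
      lo <- zz[k] + (zz[k + 1L] - zz[k]) * (thr - cc[k]) / (cc[k + 1L] - cc[k])
      break
    }
    for (k in kk:length(cc)) if (cc[k] < thr) {
      lo2 <- zz[k - 1L]
      hi <- lo2 + (zz[k] - lo2) * (cc[k - 1L] - thr) / (cc[k - 1L] - cc[k])
      break
    }
    if (is.finite(lo) && is.finite(hi)) out[j, i] <- hi - lo
  }
  out
}

#' Uniformity statistics of a maximum-contrast map
#'
#' `NaN`-aware summary of contrast variation across the field. The standard
#' deviation is the population form (`sqrt(mean((x - mean)^2))`), matching
#' the use of the map as a complete census of the field rather than a
#' sample.
#'
#' @param cmax matrix of per-subregion peak contrast.
#' @return List with `mean`, `sd`, `cv` (`sd/mean`), `min`, `max`, and
#'   `which_min`, `which_max` (row, col) indices.
#' @export
contrast_uniformity <- function(cmax) {
  v <- cmax[is.finite(cmax)]
  if (length(v) < 1L) stop("no valid entries in cmax map")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  list(mean = m, sd = s, cv = if (m > 0) s / m else NaN,
       min = min(v), max = max(v),
       which_min = which(cmax == min(v), arr.ind = TRUE)[1L, ],
       which_max = which(cmax == max(v), arr.ind = TRUE)[1L, ])
}

#' Chromatic focal offsets between channels
#'
#' Chromatic aberration shifts the best-focus surface bodily along z
#' between emission channels, so a multi-channel instrument must be
#' refocused per channel. The per-channel offset is summarized as the
#' median over the valid overlap of `z0_channel - z0_reference`, robust to
#' residual field-curvature differences; the per-pair offset maps are
#' retained.
#'
#' @param surfaces named list of `best_focus_surface` objects sharing one
#'   grid (typically one per emission filter).
#' @param reference name of the reference channel (default: first).
#' @return A `chromatic_report`: list with `reference`, `offsets_um` (named
#'   vector, offset of each channel vs the reference), `pairwise_um`
#'   (antisymmetric matrix of median offsets between all channel pairs) and
#'   `offset_maps_um` (list of per-subregion offset maps vs the reference).
#' @export
chromatic_focal_offset <- function(surfaces, reference = names(surfaces)[1L]) {
  if (is.null(names(surfaces)) || any(!nzchar(names(surfaces))))
    stop("'surfaces' must be a named list")
  if (!reference %in% names(surfaces)) stop("unknown reference channel")
  gdim <- lapply(surfaces, function(s) dim(s$z0_um))
  if (any(!vapply(gdim, identical, logical(1L), gdim[[1L]])))
    stop("all surfaces must share the same grid")
  chans <- names(surfaces)
  med_off <- function(a, b) {
    ok <- a$valid_mask & b$valid_mask
    if (sum(ok) < 3L) stop("fewer than 3 overlapping valid subregions")
    stats::median(a$z0_um[ok] - b$z0_um[ok])
  }
  ref <- surfaces[[reference]]
  offsets <- vapply(surfaces, med_off, numeric(1L), b = ref)
  maps <- lapply(surfaces, function(s) {
    m <- s$z0_um - ref$z0_um
    m[!(s$valid_mask & ref$valid_mask)] <- NA_real_
    m
  })
  pw <- outer(seq_along(chans), seq_along(chans),
              Vectorize(function(i, j) med_off(surfaces[[i]], surfaces[[j]])))
  dimnames(pw) <- list(chans, chans)
  structure(list(reference = reference, offsets_um = offsets,
                 pairwise_um = pw, offset_maps_um = maps),
            class = "chromatic_report")
}

#' @export
print.chromatic_report <- function(x, ...) {
  cat("<chromatic_report> reference channel:", x$reference, "\n")
  print(round(x$offsets_um, 2))
  invisible(x)
}

#' Magnification scale factor of a non-design tube lens
#'
#' Infinity-corrected objectives reach their nominal magnification only
#' with the tube lens focal length they were designed for; pairing them
#' with a different tube lens scales the magnification by
#' `f_tube / f_design` (e.g. a 180 mm wide-field tube lens behind an
#' objective designed for 200 mm gives a factor 180/200 = 0.9).
#'
#' @param f_tube_mm focal length of the tube lens in use, mm.
#' @param f_design_mm design tube-lens focal length of the objective, mm.
#' @return The magnification scale factor.
#' @export
tube_lens_scale <- function(f_tube_mm, f_design_mm = 200) {
  if (f_tube_mm <= 0 || f_design_mm <= 0) stop("focal lengths must be > 0")
  f_tube_mm / f_design_mm
}

#' Full field-flatness analysis of a Ronchi focus stack
#'
#' One-call pipeline: builds the subregion contrast map, estimates the
#' best-focus surface, removes the target tilt, and reports the sag,
#' maximum-contrast map and uniformity, and depth-of-field map.
#'
#' @param stack a [focus_stack()] of a back-illuminated Ronchi target.
#' @param nx_sub,ny_sub subregion grid (default 32 x 20).
#' @param refine best-focus refinement, see [best_focus_surface()].
#' @param dof_threshold relative threshold for the depth of field.
#' @return A `flatness_analysis` object with components `grid`, `cmap`,
#'   `surface`, `plane_fit`, `detrended_z0`, `sag_um`, `sag_robust_um`,
#'   `cmax_map`, `uniformity`, `dof_map_um`, `channel`. Has `print`,
#'   `summary` and `plot` methods; serialize with [write_report()].
#' @examples
#' sim <- simulate_ronchi_stack(ronchi_config(n_planes = 21, noise_sd = 0,
#'   width_px = 80, height_px = 60, grid_nx = 8, grid_ny = 6), seed = 1)
#' fa <- analyze_flatness(sim$stack, nx_sub = 8, ny_sub = 6)
#' fa$sag_um
#' @export
analyze_flatness <- function(stack, nx_sub = 32, ny_sub = 20,
                             refine = "parabolic", dof_threshold = 0.5) {
  d <- dim(stack$data)
  grid <- partition_grid(d[2L], d[1L], nx_sub, ny_sub)
  cmap <- build_contrast_map(stack, grid)
  surface <- best_focus_surface(cmap, refine = refine)
  fl <- field_flatness(surface)
  cmax <- max_contrast_map(cmap)
  structure(list(grid = grid, cmap = cmap, surface = surface,
                 plane_fit = fl$plane_fit, detrended_z0 = fl$detrended_z0,
                 sag_um = fl$sag_um, sag_robust_um = fl$sag_robust_um,
                 cmax_map = cmax, uniformity = contrast_uniformity(cmax),
                 dof_map_um = depth_of_field_map(cmap, dof_threshold),
                 channel = stack$channel),
            class = "flatness_analysis")
}

#' @export
print.flatness_analysis <- function(x, ...) {
  u <- x$uniformity
  cat("<flatness_analysis>",
      if (nzchar(x$channel)) paste0("channel '", x$channel, "'"), "\n")
  cat(sprintf("  grid            : %d x %d subregions (%d valid)\n",
              x$grid$nx_sub, x$grid$ny_sub, sum(x$surface$valid_mask)))
  cat(sprintf("  sag             : %.2f um (robust %.2f um)\n",
              x$sag_um, x$sag_robust_um))
  cat(sprintf("  tilt plane      : a0 = %.2f, ax = %.2f, ay = %.2f um\n",
              x$plane_fit[["a0"]], x$plane_fit[["ax"]], x$plane_fit[["ay"]]))
  cat(sprintf("  max contrast    : mean %.3f, CV %.3f, range [%.3f, %.3f]\n",
              u$mean, u$cv, u$min, u$max))
  cat(sprintf("  depth of field  : median %.1f um\n",
              stats::median(x$dof_map_um, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.flatness_analysis <- function(object, ...) {
  print(object)
  invisible(list(sag_um = object$sag_um, sag_robust_um = object$sag_robust_um,
                 plane_fit = object$plane_fit, uniformity = object$uniformity,
                 dof_median_um = stats::median(object$dof_map_um, na.rm = TRUE)))
}

#' @export
plot.flatness_analysis <- function(x, which = c("cmax", "best_focus", "detrended", "dof"),
                                   ...) {
  which <- match.arg(which)
  m <- switch(which, cmax = x$cmax_map, best_focus = x$surface$z0_um,
              detrended = x$detrended_z0, dof = x$dof_map_um)
  ttl <- switch(which, cmax = "Maximum contrast",
                best_focus = "Best-focus surface (um)",
                detrended = "Detrended best-focus (um)",
                dof = "Depth of field (um)")
  .plot_field_map(m, x$grid, main = ttl, ...)
  invisible(x)
}

# image() with row 1 at the top (camera convention), NaN left blank
.plot_field_map <- function(m, grid = NULL, main = "", zlim = NULL, ...) {
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(zlim)) {
    rng <- range(m, na.rm = TRUE)
    zlim <- if (diff(rng) == 0) rng + c(-1, 1) * max(abs(rng), 1) * 0.05 else rng
  }
  graphics::image(seq_len(nc), seq_len(nr), t(m[nr:1, , drop = FALSE]),
                  xlab = "subregion x", ylab = "subregion y", main = main,
                  zlim = zlim, col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
}

#' @export
report_list.flatness_analysis <- function(report) {
  list(channel = report$channel,
       grid = list(nx_sub = report$grid$nx_sub, ny_sub = report$grid$ny_sub,
                   width_px = report$grid$width_px,
                   height_px = report$grid$height_px),
       z_positions_um = report$cmap$z_positions_um,
       sag_um = report$sag_um, sag_robust_um = report$sag_robust_um,
       plane_fit = as.list(report$plane_fit),
       uniformity = report$uniformity[c("mean", "sd", "cv", "min", "max")],
       cmax_map = report$cmax_map,
       best_focus_um = report$surface$z0_um,
       detrended_z0_um = report$detrended_z0,
       dof_map_um = report$dof_map_um)
}

#' @export
report_table.flatness_analysis <- function(report) {
  g <- report$grid
  data.frame(
    iy = rep(seq_len(g$ny_sub), g$nx_sub),
    ix = rep(seq_len(g$nx_sub), each = g$ny_sub),
    center_x_px = rep(g$centers_x_px, each = g$ny_sub),
    center_y_px = rep(g$centers_y_px, g$nx_sub),
    best_focus_um = as.vector(report$surface$z0_um),
    detrended_um = as.vector(report$detrended_z0),
    cmax = as.vector(report$cmax_map),
    dof_um = as.vector(report$dof_map_um))
}

#' @export
report_list.chromatic_report <- function(report) {
  list(reference = report$reference,
       offsets_um = as.list(report$offsets_um),
       pairwise_um = report$pairwise_um,
       offset_maps_um = report$offset_maps_um)
}

#' @export
report_table.chromatic_report <- function(report) {
  data.frame(channel = names(report$offsets_um),
             offset_um = as.numeric(report$offsets_um),
             reference = report$reference)
}
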