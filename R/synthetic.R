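# Ground-truthed simulators for the three QC acquisition types:
# defocused Ronchi-ruling stacks, sub-resolution bead volumes, and
# repeated-scan pairs with planted sparse tracks.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Focus positions of a sweep
#'
#' Inclusive arithmetic sequence of focus positions, e.g. a sweep from
#' -300 to +300 um in 10 um steps gives 61 planes.
#'
#' @param z_min_um,z_max_um sweep range in micrometres, `z_max_um >= z_min_um`.
#' @param step_um positive step in micrometres.
#' @return Numeric vector `z_min, z_min + step, ...` with
#'   `floor((z_max - z_min) / step) + 1` elements.
#' @examples
#' length(generate_focus_positions(-300, 300, 10)) # 61
#' @export
generate_focus_positions <- function(z_min_um, z_max_um, step_um) {
  if (!is.finite(step_um) || step_um <= 0) stop("step_um must be > 0")
  if (z_max_um < z_min_um) stop("z_max_um must be >= z_min_um")
  n <- floor((z_max_um - z_min_um) / step_um + 1e-9) + 1
  z_min_um + (seq_len(n) - 1) * step_um
}

#' Configuration for the simulated Ronchi-ruling focus stack
#'
#' Describes a back-illuminated square-wave grating (horizontal lines,
#' default 40 line pairs per mm) imaged through a focus sweep. The local
#' contrast follows `C(x, y, z) = C_peak(x, y) * exp(-(z - z0(x, y))^2 /
#' (2 * dof_width_um^2))`, a symmetric unimodal model whose peak location
#' and amplitude -- the only quantities the analysis consumes -- are known
#' exactly. The best-focus surface is
#' `z0(x, y) = a0 + ax * x + ay * y + c2 * r^2 + c4 * r^4` with `x`, `y`
#' normalized to \[-1, 1\] across the field and `r` the radial coordinate
#' normalized so the field corner is at `r = 1`.
#'
#' @param width_px,height_px sensor size in pixels.
#' @param lp_per_mm grating frequency in line pairs per mm.
#' @param pixel_size_um lateral pixel size in micrometres; the grating
#'   period `1000 / (lp_per_mm * pixel_size_um)` must be at least 4 px.
#' @param z_start_um,z_step_um,n_planes the focus sweep.
#' @param surface_coeffs named vector `c(a0, ax, ay, c2, c4)` of best-focus
#'   surface coefficients in micrometres.
#' @param dof_width_um Gaussian half-width of contrast vs defocus (um).
#' @param cmax_field peak contrast: a single value in \[0, 1\], or
#'   `c(center, edge)` for a linear-in-`r^2` radial falloff.
#' @param mean_level mean intensity in camera counts.
#' @param noise_sd additive Gaussian (read) noise, counts.
#' @param chromatic_offset_um additive focus offset for this channel (um).
#' @param grid_nx,grid_ny subregion grid at which ground truth is sampled.
#' @return A `ronchi_config` list.
#' @export
ronchi_config <- function(width_px = 320, height_px = 200, lp_per_mm = 40,
                          pixel_size_um = 2.5, z_start_um = -300,
                          z_step_um = 10, n_planes = 61,
                          surface_coeffs = c(a0 = 0, ax = 0, ay = 0, c2 = 0, c4 = 0),
                          dof_width_um = 30, cmax_field = 0.8,
                          mean_level = 10000, noise_sd = 200,
                          chromatic_offset_um = 0,
                          grid_nx = 32, grid_ny = 20) {
  sc <- c(a0 = 0, ax = 0, ay = 0, c2 = 0, c4 = 0)
  sc[names(surface_coeffs)] <- surface_coeffs
  if (n_planes < 1) stop("n_planes must be >= 1")
  if (dof_width_um <= 0) stop("dof_width_um must be > 0")
  if (any(cmax_field < 0) || any(cmax_field > 1))
    stop("cmax_field must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  period_px <- 1000 / (lp_per_mm * pixel_size_um)
  if (period_px < 4)
    stop(sprintf("grating period %.2f px is unresolvable (< 4 px)", period_px))
  structure(list(width_px = width_px, height_px = height_px,
                 lp_per_mm = lp_per_mm, pixel_size_um = pixel_size_um,
                 z_start_um = z_start_um, z_step_um = z_step_um,
                 n_planes = n_planes, surface_coeffs = sc,
                 dof_width_um = dof_width_um, cmax_field = cmax_field,
                 mean_level = mean_level, noise_sd = noise_sd,
                 chromatic_offset_um = chromatic_offset_um,
                 grid_nx = grid_nx, grid_ny = grid_ny,
                 period_px = period_px),
            class = "ronchi_config")
}

# normalized field coordinates of points (centers in pixel units, 1-based)
.field_norm <- function(cx_px, cy_px, width_px, height_px) {
  xn <- (cx_px - width_px / 2) / (width_px / 2)
  yn <- (cy_px - height_px / 2) / (height_px / 2)
  list(x = xn, y = yn, r2 = (xn^2 + yn^2) / 2)  # corner at r = 1
}

.ronchi_z0 <- function(cfg, xn, yn) {
  sc <- cfg$surface_coeffs
  r2 <- (xn^2 + yn^2) / 2
  sc[["a0"]] + sc[["ax"]] * xn + sc[["ay"]] * yn +
    sc[["c2"]] * r2 + sc[["c4"]] * r2^2 + cfg$chromatic_offset_um
}

.ronchi_cpeak <- function(cfg, xn, yn) {
  cf <- cfg$cmax_field
  if (length(cf) == 1L) return(rep(cf, length(xn)))
  r2 <- (xn^2 + yn^2) / 2
  cf[[1L]] + (cf[[2L]] - cf[[1L]]) * r2
}

# detrended peak-to-valley of a surface sampled on grid centers
.detrended_ptv <- function(z0, xn, yn) {
  fit <- stats::lm.fit(cbind(1, xn, yn), as.vector(z0))
  diff(range(fit$residuals))
}

#' Radial coefficient giving a target field-flatness sag
#'
#' Solves for the `c2` surface coefficient such that the plane-detrended
#' peak-to-valley of the best-focus surface, sampled at the configuration's
#' subregion centers, equals `sag_um`. Linearity of the surface in `c2`
#' makes this a one-line rescaling.
#'
#' @param cfg a [ronchi_config()].
#' @param sag_um desired detrended peak-to-valley in micrometres.
#' @return The `c2` value in micrometres.
#' @export
ronchi_c2_for_sag <- function(cfg, sag_um) {
  if (sag_um == 0) return(0)
  probe <- cfg
  probe$surface_coeffs[c("c2", "c4")] <- c(1, 0)
  gt <- .ronchi_truth(probe)
  sag_um / gt$sag_um
}

.grid_centers_norm <- function(width_px, height_px, nx, ny) {
  g <- partition_grid(width_px, height_px, nx, ny)
  cx <- matrix(g$centers_x_px, ny, nx, byrow = TRUE)
  cy <- matrix(g$centers_y_px, ny, nx)
  .field_norm(cx, cy, width_px, height_px)
}

.ronchi_truth <- function(cfg) {
  nc <- .grid_centers_norm(cfg$width_px, cfg$height_px, cfg$grid_nx, cfg$grid_ny)
  z0 <- matrix(.ronchi_z0(cfg, nc$x, nc$y), cfg$grid_ny, cfg$grid_nx)
  cpk <- matrix(.ronchi_cpeak(cfg, nc$x, nc$y), cfg$grid_ny, cfg$grid_nx)
  list(z0_um = z0, cmax = cpk,
       sag_um = .detrended_ptv(z0, as.vector(nc$x), as.vector(nc$y)),
       dof_fwhm_um = 2 * cfg$dof_width_um * sqrt(2 * log(2)))
}

#' Simulate a Ronchi-ruling focus stack with known ground truth
#'
#' Renders a horizontal square-wave grating (bright/dark line pairs, edge at
#' row 1) whose local modulation falls off as a Gaussian of the defocus
#' distance from a known, possibly curved and tilted, best-focus surface.
#' Additive Gaussian read noise is applied and the image is quantized to
#' 16-bit camera counts.
#'
#' @param cfg a [ronchi_config()].
#' @param seed integer RNG seed; identical `(cfg, seed)` give bit-identical
#'   stacks.
#' @return A list with `stack` (a [focus_stack()]) and `truth`, a list with
#'   `z0_um` (true best-focus surface at subregion centers, `grid_ny` x
#'   `grid_nx`), `cmax` (true peak contrast there), `sag_um` (true detrended
#'   peak-to-valley) and `dof_fwhm_um` (true 50%-threshold depth of field).
#' @export
simulate_ronchi_stack <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ronchi_config"))
  .with_seed(seed, {
    H <- cfg$height_px; W <- cfg$width_px
    px <- .field_norm(matrix(seq_len(W) - 0.5, H, W, byrow = TRUE),
                      matrix(seq_len(H) - 0.5, H, W), W, H)
    z0 <- matrix(.ronchi_z0(cfg, px$x, px$y), H, W)
    cpk <- matrix(.ronchi_cpeak(cfg, px$x, px$y), H, W)
    phase <- ((seq_len(H) - 1) %% cfg$period_px) / cfg$period_px
    s_row <- ifelse(phase < 0.5, 1, -1)
    s_mat <- matrix(s_row, H, W)
    z <- cfg$z_start_um + (seq_len(cfg$n_planes) - 1) * cfg$z_step_um
    data <- array(0, c(H, W, cfg$n_planes))
    for (k in seq_len(cfg$n_planes)) {
      cz <- cpk * exp(-(z[k] - z0)^2 / (2 * cfg$dof_width_um^2))
      frame <- cfg$mean_level * (1 + cz * s_mat)
      if (cfg$noise_sd > 0) frame <- frame + stats::rnorm(H * W, 0, cfg$noise_sd)
      data[, , k] <- pmin(pmax(round(frame), 0), 65535)
    }
    list(stack = focus_stack(data, z, channel = "sim",
                             pixel_size_um = cfg$pixel_size_um, bits = 16L),
         truth = .ronchi_truth(cfg))
  })
}

#' Configuration for the simulated bead volume
#'
#' Sub-resolution fluorescent beads (physical diameter ~0.2 um, negligible
#' against the PSF) are modeled as 3D anisotropic Gaussian spots with
#' sub-voxel centers on a constant background with additive Gaussian noise,
#' quantized to integer counts.
#'
#' @param shape_vox named `c(z=, y=, x=)` volume size in voxels.
#' @param voxel_size_um named `c(z=, y=, x=)` voxel size in micrometres.
#' @param n_beads number of isolated beads to plant.
#' @param sigma_um named `c(x=, y=, z=)` true Gaussian widths in um.
#' @param amplitude peak bead intensity above background, counts.
#' @param background constant background level, counts.
#' @param noise_sd additive Gaussian noise, counts.
#' @param min_separation_um minimum center-to-center distance between
#'   planted isolated beads, micrometres.
#' @param cluster_fraction fraction of `n_beads` that additionally receive a
#'   near-coincident companion (planted pair ~1.5 um away); pair members are
#'   flagged in the ground truth.
#' @param margin_um minimum distance of a center from any volume face.
#' @return A `bead_config` list.
#' @export
bead_config <- function(shape_vox = c(z = 48, y = 160, x = 160),
                        voxel_size_um = c(z = 1, y = 0.5, x = 0.5),
                        n_beads = 50,
                        sigma_um = c(x = 0.64, y = 0.64, z = 1.4),
                        amplitude = 2000, background = 100, noise_sd = 100,
                        min_separation_um = 8, cluster_fraction = 0,
                        margin_um = 6) {
  if (n_beads < 0) stop("n_beads must be >= 0")
  if (any(sigma_um <= 0)) stop("sigma_um must be > 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  shape_vox <- shape_vox[c("z", "y", "x")]
  voxel_size_um <- voxel_size_um[c("z", "y", "x")]
  sigma_um <- sigma_um[c("x", "y", "z")]
  structure(list(shape_vox = shape_vox, voxel_size_um = voxel_size_um,
                 n_beads = n_beads, sigma_um = sigma_um, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 min_separation_um = min_separation_um,
                 cluster_fraction = cluster_fraction, margin_um = margin_um),
            class = "bead_config")
}

#' Simulate a fluorescent bead volume with known ground truth
#'
#' @param cfg a [bead_config()].
#' @param seed integer RNG seed.
#' @return A list with `volume` (a [qc_volume()]) and `truth`, a data.frame
#'   with one row per planted bead: sub-voxel center in voxel units
#'   (`z_vox`, `y_vox`, `x_vox`, 1-based) and micrometres, true sigmas, true
#'   lateral/axial FWHM (um) and `cluster` (TRUE for planted pair members).
#' @export
simulate_bead_volume <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "bead_config"))
  .with_seed(seed, {
    dims <- cfg$shape_vox[c("y", "x", "z")]
    vol <- array(0, unname(dims))
    vs <- cfg$voxel_size_um
    ext_um <- c(z = unname(cfg$shape_vox[["z"]] * vs[["z"]]),
                y = unname(cfg$shape_vox[["y"]] * vs[["y"]]),
                x = unname(cfg$shape_vox[["x"]] * vs[["x"]]))
    if (any(ext_um <= 2 * cfg$margin_um) && cfg$n_beads > 0)
      stop("volume too small for the bead margin")
    # rejection-sample isolated centers (um coordinates)
    centers <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
    tries <- 0L
    while (nrow(centers) < cfg$n_beads) {
      if ((tries <- tries + 1L) > 200L * max(cfg$n_beads, 1L))
        stop("bead placement failed: min_separation_um too large for volume")
      p <- c(stats::runif(1, cfg$margin_um, ext_um[["z"]] - cfg$margin_um),
             stats::runif(1, cfg$margin_um, ext_um[["y"]] - cfg$margin_um),
             stats::runif(1, cfg$margin_um, ext_um[["x"]] - cfg$margin_um))
      if (nrow(centers) == 0L ||
          min(sqrt(colSums((t(centers) - p)^2))) >= cfg$min_separation_um)
        centers <- rbind(centers, p)
    }
    cluster <- rep(FALSE, nrow(centers))
    n_pairs <- round(cfg$cluster_fraction * cfg$n_beads)
    if (n_pairs > 0) {
      hosts <- seq_len(min(n_pairs, nrow(centers)))
      for (h in hosts) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        centers <- rbind(centers, centers[h, ] + 1.5 * dir)
        cluster[h] <- TRUE
        cluster <- c(cluster, TRUE)
      }
    }
    sig_vox <- c(z = cfg$sigma_um[["z"]] / vs[["z"]],
                 y = cfg$sigma_um[["y"]] / vs[["y"]],
                 x = cfg$sigma_um[["x"]] / vs[["x"]])
    if (nrow(centers) > 0) for (b in seq_len(nrow(centers))) {
      cz <- centers[b, "z"] / vs[["z"]] + 0.5   # voxel-center coords, 1-based
      cy <- centers[b, "y"] / vs[["y"]] + 0.5
      cx <- centers[b, "x"] / vs[["x"]] + 0.5
      rz <- max(1L, floor(cz - 4 * sig_vox[["z"]])):min(dim(vol)[3], ceiling(cz + 4 * sig_vox[["z"]]))
      ry <- max(1L, floor(cy - 4 * sig_vox[["y"]])):min(dim(vol)[1], ceiling(cy + 4 * sig_vox[["y"]]))
      rx <- max(1L, floor(cx - 4 * sig_vox[["x"]])):min(dim(vol)[2], ceiling(cx + 4 * sig_vox[["x"]]))
      gz <- exp(-(rz - cz)^2 / (2 * sig_vox[["z"]]^2))
      gy <- exp(-(ry - cy)^2 / (2 * sig_vox[["y"]]^2))
      gx <- exp(-(rx - cx)^2 / (2 * sig_vox[["x"]]^2))
      blob <- cfg$amplitude * (gy %o% gx %o% gz)
      vol[ry, rx, rz] <- vol[ry, rx, rz] + blob
    }
    vol <- vol + cfg$background
    if (cfg$noise_sd > 0) vol <- vol + stats::rnorm(length(vol), 0, cfg$noise_sd)
    vol <- pmin(pmax(round(vol), 0), 65535)
    fwhm <- sigma_to_fwhm(1)
    truth <- data.frame(
      z_vox = centers[, "z"] / vs[["z"]] + 0.5,
      y_vox = centers[, "y"] / vs[["y"]] + 0.5,
      x_vox = centers[, "x"] / vs[["x"]] + 0.5,
      z_um = centers[, "z"], y_um = centers[, "y"], x_um = centers[, "x"],
      sigma_x_um = cfg$sigma_um[["x"]], sigma_y_um = cfg$sigma_um[["y"]],
      sigma_z_um = cfg$sigma_um[["z"]],
      fwhm_lateral_um = fwhm * sqrt(cfg$sigma_um[["x"]] * cfg$sigma_um[["y"]]),
      fwhm_z_um = fwhm * cfg$sigma_um[["z"]],
      cluster = cluster)
    list(volume = qc_volume(vol, vs), truth = truth)
  })
}

#' Configuration for a simulated repeated-scan pair
#'
#' Sparse bright "tracks" -- runs of single bright voxels stepping
#' anti-diagonally one voxel per plane across several consecutive planes --
#' are planted identically in two volumes which then receive independent
#' Gaussian background noise, emulating two consecutive scans of the same
#' specimen. An optional small rigid offset between the scans models
#' imperfect stage reproducibility.
#'
#' @param shape_vox named `c(z=, y=, x=)` volume size in voxels.
#' @param n_tracks number of tracks to plant.
#' @param track_length_planes planes spanned by each track (default 5).
#' @param track_intensity mean intensity of track voxels, counts.
#' @param background_mean,background_sd background level and noise, counts.
#' @param registration_offset_vox named `c(z=, y=, x=)` integer shift of
#'   scan B relative to scan A, each component with absolute value <= 3.
#' @return A `track_config` list. The track signal-to-noise ratio is
#'   `(track_intensity - background_mean) / background_sd`.
#' @export
track_config <- function(shape_vox = c(z = 48, y = 64, x = 64),
                         n_tracks = 3, track_length_planes = 5,
                         track_intensity = 150,
                         background_mean = 100, background_sd = 5,
                         registration_offset_vox = c(z = 0, y = 0, x = 0)) {
  if (track_length_planes < 1) stop("track_length_planes must be >= 1")
  if (background_sd < 0) stop("background_sd must be >= 0")
  if (any(abs(registration_offset_vox) > 3))
    stop("registration_offset_vox components must be <= 3 in magnitude")
  if (track_length_planes > shape_vox[["z"]])
    stop("track longer than volume depth")
  structure(list(shape_vox = shape_vox[c("z", "y", "x")], n_tracks = n_tracks,
                 track_length_planes = track_length_planes,
                 track_intensity = track_intensity,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 registration_offset_vox = registration_offset_vox[c("z", "y", "x")]),
            class = "track_config")
}

#' Simulate a pair of repeated scans with planted tracks
#'
#' @param cfg a [track_config()].
#' @param seed integer RNG seed.
#' @return A list with `scan_a`, `scan_b` (each a [qc_volume()]) and
#'   `truth`: a list of per-track voxel coordinate matrices (columns
#'   `z`, `y`, `x`, 1-based) for scan A, plus the registration offset that
#'   maps them into scan B.
#' @export
simulate_scan_pair <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "track_config"))
  .with_seed(seed, {
    d <- cfg$shape_vox
    off <- cfg$registration_offset_vox
    dims <- unname(d[c("y", "x", "z")])
    L <- cfg$track_length_planes
    margin_lat <- 16L; margin_z <- 4L
    tracks <- list()
    starts <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (length(tracks) < cfg$n_tracks) {
      if ((tries <- tries + 1L) > 500L * max(cfg$n_tracks, 1L))
        stop("track placement failed; volume too small")
      z0 <- sample(seq(margin_z + 1, d[["z"]] - margin_z - L + 1), 1L)
      y0 <- sample(seq(margin_lat + 1, d[["y"]] - margin_lat - L), 1L)
      x0 <- sample(seq(margin_lat + 1, d[["x"]] - margin_lat - L), 1L)
      sy <- sample(c(-1L, 1L), 1L); sx <- sample(c(-1L, 1L), 1L)
      if (sy < 0) y0 <- y0 + L - 1L
      if (sx < 0) x0 <- x0 + L - 1L
      if (nrow(starts) > 0 &&
          min(sqrt(colSums((t(starts) - c(z0, y0, x0))^2))) < 25) next
      starts <- rbind(starts, c(z0, y0, x0))
      i <- 0:(L - 1L)
      tracks[[length(tracks) + 1L]] <-
        cbind(z = z0 + i, y = y0 + sy * i, x = x0 + sx * i)
    }
    render <- function(shift) {
      vol <- array(stats::rnorm(prod(dims), cfg$background_mean, cfg$background_sd),
                   dims)
      for (tr in tracks) {
        zz <- tr[, "z"] + shift[["z"]]; yy <- tr[, "y"] + shift[["y"]]
        xx <- tr[, "x"] + shift[["x"]]
        keep <- zz >= 1 & zz <= dims[3] & yy >= 1 & yy <= dims[1] &
          xx >= 1 & xx <= dims[2]
        vol[cbind(yy[keep], xx[keep], zz[keep])] <-
          cfg$track_intensity +
          stats::rnorm(sum(keep), 0, cfg$background_sd)
      }
      pmin(pmax(round(vol), 0), 65535)
    }
    a <- render(c(z = 0, y = 0, x = 0))
    b <- render(off)
    list(scan_a = qc_volume(a), scan_b = qc_volume(b),
         truth = list(tracks_a = tracks, offset_b = off))
  })
}
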