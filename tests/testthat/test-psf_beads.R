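test_that("sigma-to-FWHM conversion follows the Gaussian closed form", {
  expect_equal(sigma_to_fwhm(1), 2.35482, tolerance = 1e-5)
  expect_equal(sigma_to_fwhm(2), 4.70964, tolerance = 1e-5)
  expect_error(sigma_to_fwhm(0), "> 0")
  expect_error(sigma_to_fwhm(-1), "> 0")
})

test_that("detection finds a lone noiseless bead and nothing in pure noise", {
  sim <- simulate_bead_volume(bead_config(n_beads = 1, noise_sd = 0), 1)
  cands <- detect_bead_candidates(sim$volume)
  expect_equal(nrow(cands), 1)
  expect_lt(abs(cands$z_vox - sim$truth$z_vox), 1)
  expect_lt(abs(cands$y_vox - sim$truth$y_vox), 1)
  expect_lt(abs(cands$x_vox - sim$truth$x_vox), 1)
  # pure noise at 8 sigma: expected false positives << 1 for 64^3 voxels
  set.seed(99)
  noise <- qc_volume(pmax(round(array(rnorm(64^3, 100, 10), c(64, 64, 64))), 0))
  expect_equal(nrow(detect_bead_candidates(noise, min_snr = 8)), 0)
})

test_that("detection recovers nearly all beads at SNR 20", {
  sim <- simulate_bead_volume(bead_config(n_beads = 50), 6)
  cands <- detect_bead_candidates(sim$volume, min_snr = 8)
  expect_gte(nrow(cands), 49)
})

test_that("cluster filtering equals the brute-force pairwise oracle", {
  mk <- function(z, y, x) data.frame(z_um = z, y_um = y, x_um = x)
  pair <- mk(c(10, 10), c(10, 10.8), c(10, 10.5))  # ~1 um apart
  expect_equal(nrow(filter_bead_clusters(pair, 5)), 0)
  iso <- mk(c(5, 25, 45), c(5, 25, 45), c(5, 25, 45))
  expect_equal(filter_bead_clusters(iso, 5), iso, ignore_attr = TRUE)
  # chain A-B-C with only A-B close: C survives
  chain <- mk(c(10, 12, 30), c(10, 11, 30), c(10, 10, 30))
  kept <- filter_bead_clusters(chain, 5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$z_um, 30)
  set.seed(8)
  for (rep in 1:10) {
    cands <- mk(runif(60, 0, 50), runif(60, 0, 50), runif(60, 0, 50))
    sep <- runif(1, 2, 12)
    expect_equal(filter_bead_clusters(cands, sep), oracle_filter(cands, sep),
                 ignore_attr = TRUE)
  }
  expect_error(filter_bead_clusters(iso, -1), ">= 0")
})

test_that("Gaussian fitting recovers noiseless widths within 1%", {
  cfg <- bead_config(n_beads = 1, noise_sd = 0,
                     voxel_size_um = c(z = 1, y = 1, x = 1),
                     sigma_um = c(x = 1, y = 1, z = 2),
                     shape_vox = c(z = 48, y = 48, x = 48),
                     margin_um = 12)
  sim <- simulate_bead_volume(cfg, 2)
  cand <- detect_bead_candidates(sim$volume)
  fit <- fit_bead_gaussian(sim$volume, cand[1, ],
                           window_halfwidth_vox = c(z = 9, y = 6, x = 6))
  expect_equal(fit$status, "ok")
  expect_equal(fit$sigma_x_um, 1, tolerance = 0.01)
  expect_equal(fit$sigma_y_um, 1, tolerance = 0.01)
  expect_equal(fit$sigma_z_um, 2, tolerance = 0.01)
  expect_equal(fit$fwhm_z_um, 4.71, tolerance = 0.01)
  expect_equal(fit$fwhm_lateral_um, sqrt(fit$fwhm_x_um * fit$fwhm_y_um))
  expect_lt(abs(fit$z_um - sim$truth$z_um), 0.2)
})

test_that("edge beads and featureless windows are rejected, not fitted", {
  sim <- simulate_bead_volume(bead_config(n_beads = 1, noise_sd = 0), 3)
  corner <- data.frame(z_vox = 2L, y_vox = 2L, x_vox = 2L)
  expect_equal(fit_bead_gaussian(sim$volume, corner)$status, "edge")
  flat <- qc_volume(array(100, c(32, 32, 32)))
  center <- data.frame(z_vox = 16L, y_vox = 16L, x_vox = 16L)
  expect_equal(fit_bead_gaussian(flat, center)$status, "poor_fit")
})

test_that("fitted widths are invariant under intensity gain and offset", {
  sim <- simulate_bead_volume(bead_config(n_beads = 1, noise_sd = 0), 5)
  cand <- detect_bead_candidates(sim$volume)[1, ]
  f1 <- fit_bead_gaussian(sim$volume, cand)
  scaled <- qc_volume(sim$volume$data * 2.5 + 40, sim$volume$voxel_size_um)
  f2 <- fit_bead_gaussian(scaled, cand)
  expect_equal(f2$sigma_x_um, f1$sigma_x_um, tolerance = 1e-6)
  expect_equal(f2$sigma_y_um, f1$sigma_y_um, tolerance = 1e-6)
  expect_equal(f2$sigma_z_um, f1$sigma_z_um, tolerance = 1e-6)
})

test_that("the PSF summary reports means, spread and histograms over ok fits", {
  sim <- simulate_bead_volume(bead_config(n_beads = 30), 7)
  rep <- measure_psf(sim$volume)
  expect_lte(rep$n_kept, rep$n_detected)
  truth_lat <- sim$truth$fwhm_lateral_um[1]
  expect_equal(rep$lateral_um$mean, truth_lat, tolerance = 0.05 * truth_lat)
  expect_equal(sum(rep$lateral_um$hist$counts), rep$n_kept)
  one <- rep$fits[rep$fits$status == "ok", ][1, ]
  s1 <- summarize_psf(one)
  expect_equal(s1$lateral_um$mean, one$fwhm_lateral_um)
  expect_equal(s1$lateral_um$sd, 0)
  bad <- one; bad$status <- "edge"
  expect_error(summarize_psf(bad), "no fits")
})
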