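test_that("the subregion grid uses floor boundaries with full coverage", {
  g <- partition_grid(5056, 2960, 32, 20)
  expect_equal(unique(diff(g$col_bounds)), 158)
  expect_equal(unique(diff(g$row_bounds)), 148)
  g1 <- partition_grid(100, 100, 1, 1)
  expect_equal(g1$col_bounds, c(0, 100))
  expect_equal(g1$row_bounds, c(0, 100))
  g3 <- partition_grid(10, 10, 3, 3)
  expect_equal(g3$col_bounds, c(0, 3, 6, 10))
  expect_equal(diff(g3$col_bounds), c(3, 3, 4))
  expect_error(partition_grid(5, 5, 10, 2), "more subregions")
  # sizes never differ by more than 1 px
  set.seed(1)
  for (rep in 1:20) {
    w <- sample(50:500, 1); n <- sample(2:30, 1)
    g <- partition_grid(w, w, n, n)
    expect_lte(diff(range(diff(g$col_bounds))), 1)
  }
})

test_that("percentile contrast matches the interpolation oracle and edge cases", {
  expect_equal(subregion_contrast(rep(c(0, 1), 100)), 1.0)
  expect_equal(subregion_contrast(rep(5, 10)), 0.0)
  expect_equal(subregion_contrast(1:100), oracle_contrast(1:100), tolerance = 1e-12)
  expect_equal(subregion_contrast(1:100), (99.01 - 1.99) / (99.01 + 1.99),
               tolerance = 1e-12)
  expect_true(is.nan(subregion_contrast(c(0, 0, 0))))
  expect_error(subregion_contrast(numeric(0)), "at least 2")
  expect_error(subregion_contrast(c(1, -2)), "non-negative")
  set.seed(2)
  for (rep in 1:20) {
    v <- rgamma(sample(10:500, 1), 2, 0.01)
    expect_equal(subregion_contrast(v), oracle_contrast(v), tolerance = 1e-12)
  }
})

test_that("contrast is gain-invariant and strictly reduced by an offset", {
  set.seed(3)
  for (rep in 1:20) {
    v <- rgamma(200, 2, 0.01)
    c0 <- subregion_contrast(v)
    expect_equal(subregion_contrast(v * runif(1, 0.1, 50)), c0, tolerance = 1e-12)
    expect_lt(subregion_contrast(v + runif(1, 1, 1000)), c0)
  }
})

test_that("the 3D contrast map has the documented shape and flags saturation", {
  sim <- simulate_ronchi_stack(small_ronchi(n_planes = 5), 1)
  cm <- build_contrast_map(sim$stack, partition_grid(160, 100, 16, 10))
  expect_equal(dim(cm$values), c(10, 16, 5))
  expect_true(all(cm$values >= 0 & cm$values <= 1, na.rm = TRUE))
  # constant frames give an all-zero map
  flat <- focus_stack(array(7, c(20, 20, 3)), c(0, 10, 20))
  cmf <- build_contrast_map(flat, partition_grid(20, 20, 2, 2))
  expect_true(all(cmf$values == 0))
  # a clipped subregion is NaN in that plane
  arr <- array(sample(100:200, 20 * 20 * 2, replace = TRUE), c(20, 20, 2))
  arr[1:10, 1:10, 1] <- 65535
  sat <- focus_stack(arr, c(0, 10), bits = 16L)
  cms <- build_contrast_map(sat, partition_grid(20, 20, 2, 2))
  expect_true(is.nan(cms$values[1, 1, 1]))
  expect_false(anyNA(cms$values[, , 2]))
  expect_error(build_contrast_map(sim$stack, partition_grid(64, 64, 4, 4)),
               "does not match")
})

test_that("the maximum-contrast map is tip/tilt invariant", {
  cfg <- small_ronchi(noise_sd = 0, cmax_field = 0.8)
  cm0 <- build_contrast_map(simulate_ronchi_stack(cfg, 1)$stack,
                            partition_grid(160, 100, 16, 10))
  m0 <- max_contrast_map(cm0)
  expect_lt(max(abs(m0 - 0.8) / 0.8), 0.02)
  cfg$surface_coeffs[c("ax", "ay")] <- c(30, 20)
  m1 <- max_contrast_map(build_contrast_map(simulate_ronchi_stack(cfg, 1)$stack,
                                            partition_grid(160, 100, 16, 10)))
  expect_lt(max(abs(m1 - m0) / m0), 0.02)
  # single-plane map: identity
  one <- build_contrast_map(simulate_ronchi_stack(small_ronchi(n_planes = 1), 1)$stack,
                            partition_grid(160, 100, 16, 10))
  expect_equal(max_contrast_map(one), one$values[, , 1])
})

test_that("best-focus estimation is exact at a sampled symmetric peak", {
  z <- seq(0, 100, by = 10)
  prof <- exp(-(z - 50)^2 / (2 * 20^2))
  vals <- array(rep(prof, each = 1), c(1, 1, length(z)))
  cm <- structure(list(values = vals, z_positions_um = z,
                       grid = partition_grid(10, 10, 1, 1), channel = ""),
                  class = "contrast_map")
  for (refine in c("argmax", "parabolic", "gaussian")) {
    s <- best_focus_surface(cm, refine = refine)
    expect_equal(s$z0_um[1, 1], 50, tolerance = 1e-6)
  }
})

test_that("a simulated tilted surface is recovered within half a z-step", {
  cfg <- small_ronchi(noise_sd = 0,
                      surface_coeffs = c(a0 = 10, ax = 30, ay = 0, c2 = 0, c4 = 0))
  sim <- simulate_ronchi_stack(cfg, 1)
  s <- best_focus_surface(build_contrast_map(sim$stack,
                                             partition_grid(160, 100, 16, 10)))
  err <- abs(s$z0_um - sim$truth$z0_um)
  expect_lt(max(err[s$valid_mask]), cfg$z_step_um / 2)
})

test_that("boundary peaks are masked invalid", {
  z <- seq(0, 50, by = 10)
  vals <- array(seq(0.1, 0.6, length.out = 6), c(1, 1, 6))  # rising to the edge
  cm <- structure(list(values = vals, z_positions_um = z,
                       grid = partition_grid(10, 10, 1, 1), channel = ""),
                  class = "contrast_map")
  expect_error(best_focus_surface(cm), "no valid subregion")
})

test_that("tilt-plane fitting reproduces exact planes and symmetric zeros", {
  sim <- simulate_ronchi_stack(small_ronchi(noise_sd = 0), 1)
  s <- best_focus_surface(build_contrast_map(sim$stack,
                                             partition_grid(160, 100, 16, 10)))
  g <- s$grid
  xn <- matrix(g$centers_x_norm, g$ny_sub, g$nx_sub, byrow = TRUE)
  yn <- matrix(g$centers_y_norm, g$ny_sub, g$nx_sub)
  s$z0_um <- 5 + 0.1 * xn + 0.2 * yn
  s$valid_mask[] <- TRUE
  expect_equal(fit_tilt_plane(s), c(a0 = 5, ax = 0.1, ay = 0.2), tolerance = 1e-9)
  s$z0_um[] <- 3.5
  expect_equal(fit_tilt_plane(s), c(a0 = 3.5, ax = 0, ay = 0), tolerance = 1e-9)
  s$z0_um <- xn^2 + yn^2   # symmetric paraboloid: slopes vanish
  pf <- fit_tilt_plane(s)
  expect_equal(unname(pf[c("ax", "ay")]), c(0, 0), tolerance = 1e-9)
  # detrending a pure plane leaves zero sag
  s$z0_um <- 5 + 0.1 * xn + 0.2 * yn
  expect_equal(field_flatness(s)$sag_um, 0, tolerance = 1e-9)
  # detrended surface has no residual plane component
  s$z0_um <- 5 + 0.1 * xn + 0.2 * yn + 40 * (xn^2 + yn^2)
  fl <- field_flatness(s)
  s2 <- s; s2$z0_um <- fl$detrended_z0
  expect_lt(max(abs(fit_tilt_plane(s2))), 1e-9)
})

test_that("depth of field recovers the Gaussian FWHM and its limits", {
  cfg <- small_ronchi(noise_sd = 0, dof_width_um = 30)
  sim <- simulate_ronchi_stack(cfg, 1)
  cm <- build_contrast_map(sim$stack, partition_grid(160, 100, 16, 10))
  dof <- depth_of_field_map(cm, 0.5)
  expect_lt(max(abs(dof - 2 * 30 * sqrt(2 * log(2))) / (2 * 30 * sqrt(2 * log(2)))),
            0.05)
  expect_lt(max(depth_of_field_map(cm, 0.999)), cfg$z_step_um)
  # zero-contrast subregion is flagged NaN
  flat <- focus_stack(array(7, c(20, 20, 5)), seq(0, 40, 10))
  cmf <- build_contrast_map(flat, partition_grid(20, 20, 2, 2))
  expect_true(all(is.nan(depth_of_field_map(cmf))))
  expect_error(depth_of_field_map(cm, 0), "rel_threshold")
})

test_that("uniformity statistics are population moments, NaN-aware", {
  u <- contrast_uniformity(matrix(0.8, 4, 4))
  expect_equal(u$mean, 0.8); expect_equal(u$cv, 0)
  u2 <- contrast_uniformity(matrix(c(0.6, 1.0), 2, 2))
  expect_equal(u2$mean, 0.8); expect_equal(u2$sd, 0.2)
  u3 <- contrast_uniformity(matrix(c(0.5, NaN), 1, 2))
  expect_equal(u3$sd, 0)
  expect_error(contrast_uniformity(matrix(NaN, 2, 2)), "no valid")
})

test_that("chromatic offsets are medians, antisymmetric, zero on identity", {
  sim <- simulate_ronchi_stack(small_ronchi(noise_sd = 0), 1)
  s <- best_focus_surface(build_contrast_map(sim$stack,
                                             partition_grid(160, 100, 16, 10)))
  sB <- s; sB$z0_um <- s$z0_um + 400
  rep <- chromatic_focal_offset(list(blue = s, red = sB), "blue")
  expect_equal(unname(rep$offsets_um["blue"]), 0)
  expect_equal(unname(rep$offsets_um["red"]), 400)
  expect_equal(rep$pairwise_um["blue", "red"], -rep$pairwise_um["red", "blue"])
  expect_equal(diag(rep$pairwise_um), c(blue = 0, red = 0))
  expect_error(chromatic_focal_offset(list(s, sB)), "named")
})

test_that("shifting all z positions shifts z0 and preserves sag, DOF, Cmax", {
  cfg <- small_ronchi(noise_sd = 100)
  cfg$surface_coeffs[["c2"]] <- ronchi_c2_for_sag(cfg, 60)
  sim <- simulate_ronchi_stack(cfg, 7)
  st2 <- sim$stack
  st2$z_positions_um <- st2$z_positions_um + 123.4
  fa1 <- analyze_flatness(sim$stack, 16, 10)
  fa2 <- analyze_flatness(st2, 16, 10)
  expect_equal(fa2$surface$z0_um, fa1$surface$z0_um + 123.4, tolerance = 1e-9)
  expect_equal(fa2$sag_um, fa1$sag_um, tolerance = 1e-9)
  expect_equal(fa2$cmax_map, fa1$cmax_map, tolerance = 1e-12)
  expect_equal(fa2$dof_map_um, fa1$dof_map_um, tolerance = 1e-9)
})

test_that("a non-design tube lens scales magnification by the focal ratio", {
  expect_equal(tube_lens_scale(180, 200), 0.9)
  expect_equal(tube_lens_scale(200, 200), 1)
  expect_error(tube_lens_scale(-1), "> 0")
})
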