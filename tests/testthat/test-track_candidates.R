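test_that("background estimation matches sample statistics", {
  const <- array(100, c(8, 8, 4))
  bg <- estimate_background(const)
  expect_equal(bg$mean, 100); expect_equal(bg$sd, 0)
  expect_equal(bg$n_frames_used, 4)
  set.seed(21)
  frames <- array(rnorm(64 * 64 * 350, 100, 5), c(64, 64, 350))
  bg2 <- estimate_background(frames)
  expect_equal(bg2$mean, 100, tolerance = 0.001)   # +/- 0.1 at this n
  expect_equal(bg2$sd, 5, tolerance = 0.02)
  expect_equal(bg2$n_frames_used, 350)
  one <- estimate_background(matrix(50, 4, 4))
  expect_equal(one$n_frames_used, 1)
  expect_error(estimate_background(array(numeric(0), c(0, 0, 0))), "no frames")
})

test_that("cluster finding respects the sigma threshold and size cut", {
  sim <- simulate_scan_pair(track_config(n_tracks = 1), 11)
  bg <- estimate_background(sim$scan_a, robust = TRUE)
  cl <- find_structure_clusters(sim$scan_a, bg, k_sigma = 5, min_voxels = 4)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_planes_spanned, 5)
  expect_equal(cl[[1]]$n_voxels, 5)
  # pure background: no clusters at k = 5
  sim0 <- simulate_scan_pair(track_config(n_tracks = 0), 12)
  expect_length(find_structure_clusters(sim0$scan_a,
                                        estimate_background(sim0$scan_a, robust = TRUE)),
                0)
  # a 3-voxel blob fails min_voxels = 4
  v <- array(100, c(16, 16, 8))
  v[cbind(8:10, 8, 4)] <- 200
  blob <- qc_volume(v)
  bgc <- structure(list(mean = 100, sd = 2, n_frames_used = 1),
                   class = "background_model")
  expect_length(find_structure_clusters(blob, bgc, 5, 4), 0)
  expect_length(find_structure_clusters(blob, bgc, 5, 3), 1)
  expect_error(find_structure_clusters(blob, bgc, -1), ">= 0")
})

test_that("NCC hits 1 on an exact copy and -1 on a negation", {
  set.seed(31)
  tmpl <- array(runif(5 * 5 * 3, 10, 50), c(5, 5, 3))
  search <- array(runif(12 * 12 * 8, 10, 50), c(12, 12, 8))
  search[4:8, 6:10, 3:5] <- tmpl
  m <- ncc_map(tmpl, search)
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_equal(max(m), 1, tolerance = 1e-12)
  expect_equal(unname(pk), c(4, 6, 3))
  neg <- max(tmpl) + min(tmpl) - tmpl   # affine negation
  expect_equal(ncc_map(neg, search)[4, 6, 3], -1, tolerance = 1e-12)
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
  expect_error(ncc_map(search, tmpl), "larger")
  expect_error(ncc_map(array(1, c(3, 3, 3)), search), "zero-variance")
})

test_that("NCC agrees with the triple-loop oracle to 1e-10", {
  set.seed(32)
  for (rep in 1:5) {
    tmpl <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
    search <- array(rnorm(10 * 9 * 8), c(10, 9, 8))
    expect_lt(max(abs(ncc_map(tmpl, search) - oracle_ncc(tmpl, search))), 1e-10)
  }
})

test_that("NCC is invariant under affine intensity transforms", {
  set.seed(33)
  tmpl <- array(rnorm(5 * 5 * 4, 100, 10), c(5, 5, 4))
  search <- array(rnorm(11 * 11 * 9, 100, 10), c(11, 11, 9))
  m0 <- ncc_map(tmpl, search)
  expect_lt(max(abs(ncc_map(tmpl * 3.7 + 55, search) - m0)), 1e-6)
  expect_lt(max(abs(ncc_map(tmpl, search * 0.01 + 7) - m0)), 1e-6)
})

test_that("the NCC null on structureless noise is centered at zero", {
  mus <- vapply(1:8, function(s) {
    sim <- simulate_scan_pair(track_config(n_tracks = 0), s)
    tmpl <- sim$scan_a$data[25:33, 25:33, 20:26]
    search <- sim$scan_b$data[15:43, 15:43, 14:32]
    mean(ncc_map(tmpl, search))
  }, numeric(1))
  expect_lt(abs(mean(mus)), 3 * sd(mus) / sqrt(length(mus)))
})

test_that("self-matching scans flag every cluster with peak 1", {
  sim <- simulate_scan_pair(track_config(n_tracks = 2), 13)
  bg <- estimate_background(sim$scan_a, robust = TRUE)
  cl <- find_structure_clusters(sim$scan_a, bg)
  sc <- score_candidate(cl[[1]], sim$scan_a, sim$scan_a)
  expect_equal(sc$ncc_peak, 1, tolerance = 1e-12)
  expect_true(sc$flagged)
  expect_equal(unname(sc$peak_offset_vox), c(0, 0, 0))
  rep <- validate_scan_pair(sim$scan_a, sim$scan_a)
  expect_equal(rep$n_confirmed, rep$n_clusters_a)
})

test_that("planted tracks are confirmed at their ground-truth locations", {
  cfg <- track_config(n_tracks = 3,
                      registration_offset_vox = c(z = 0, y = 1, x = -1))
  sim <- simulate_scan_pair(cfg, 14)
  rep <- validate_scan_pair(sim$scan_a, sim$scan_b)
  expect_equal(rep$n_confirmed, 3)
  cents <- t(vapply(sim$truth$tracks_a,
                    function(tr) colMeans(tr[, c("z", "y", "x")]), numeric(3)))
  for (n in seq_len(nrow(rep$candidates))) {
    d <- sqrt(colSums((t(cents) - unlist(rep$candidates[n, c("z", "y", "x")]))^2))
    expect_lt(min(d), 2)
  }
  # pure-noise pairs confirm nothing
  sim0 <- simulate_scan_pair(track_config(n_tracks = 0), 15)
  expect_equal(validate_scan_pair(sim0$scan_a, sim0$scan_b)$n_confirmed, 0)
})

test_that("a structure present in only one scan is not flagged", {
  sim <- simulate_scan_pair(track_config(n_tracks = 1), 16)
  noise <- simulate_scan_pair(track_config(n_tracks = 0), 17)$scan_a
  bg <- estimate_background(sim$scan_a, robust = TRUE)
  cl <- find_structure_clusters(sim$scan_a, bg)
  sc <- score_candidate(cl[[1]], sim$scan_a, noise)
  expect_false(sc$flagged)
})
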