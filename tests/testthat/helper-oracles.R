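# Independent oracles used to cross-check the implementation.

# sorted-order linear-interpolation percentile: rank = 1 + q/100 * (n - 1)
oracle_percentile <- function(x, q) {
  xs <- sort(x)
  h <- 1 + q / 100 * (length(xs) - 1)
  lo <- floor(h); hi <- ceiling(h)
  (1 - (h - lo)) * xs[lo] + (h - lo) * xs[hi]
}

oracle_contrast <- function(values) {
  p1 <- oracle_percentile(values, 1)
  p99 <- oracle_percentile(values, 99)
  if (p1 + p99 == 0) return(NaN)
  (p99 - p1) / (p99 + p1)
}

# direct triple-loop normalized cross-correlation
oracle_ncc <- function(template, search) {
  dt <- dim(template); ds <- dim(search)
  nd <- ds - dt + 1L
  out <- array(NA_real_, nd)
  for (j in seq_len(nd[1])) for (i in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    w <- search[j:(j + dt[1] - 1), i:(i + dt[2] - 1), k:(k + dt[3] - 1)]
    out[j, i, k] <- stats::cor(as.vector(template), as.vector(w))
  }
  out
}

# O(n^2) pairwise-distance cluster filter: drop both members of close pairs
oracle_filter <- function(candidates, min_sep) {
  n <- nrow(candidates)
  drop <- logical(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    d <- sqrt((candidates$z_um[a] - candidates$z_um[b])^2 +
              (candidates$y_um[a] - candidates$y_um[b])^2 +
              (candidates$x_um[a] - candidates$x_um[b])^2)
    if (d < min_sep) drop[a] <- TRUE
  }
  candidates[!drop, , drop = FALSE]
}

# small ronchi configuration used across tests (fast but non-trivial)
small_ronchi <- function(...) {
  args <- list(width_px = 160, height_px = 100, grid_nx = 16, grid_ny = 10,
               n_planes = 41, z_start_um = -200, z_step_um = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(ronchi_config, args)
}
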