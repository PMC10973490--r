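# Detection and statistical validation of sparse fluorescent structures
# (e.g. radiation-induced color centers) by cross-correlating clusters
# found in one scan against a repeated scan of the same specimen.

#' Estimate the background model from dark or blank frames
#'
#' @param frames a [qc_volume()], [focus_stack()] or plain array of
#'   dark-frame / blank-control images.
#' @param robust if `TRUE`, use median and `1.4826 * MAD` instead of mean
#'   and standard deviation.
#' @return A `background_model`: list with `mean`, `sd`, `n_frames_used`.
#' @export
estimate_background <- function(frames, robust = FALSE) {
  v <- if (is.list(frames)) frames$data else frames
  if (length(v) == 0L) stop("no frames provided")
  n_frames <- if (is.array(v) && length(dim(v)) == 3L) dim(v)[3L] else 1L
  m <- if (robust) stats::median(v) else mean(v)
  s <- if (robust) stats::mad(v) else stats::sd(as.vector(v))
  if (is.na(s)) s <- 0
  structure(list(mean = m, sd = s, n_frames_used = n_frames),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> mean %.2f, sd %.3f (%d frame(s))\n",
              x$mean, x$sd, x$n_frames_used))
  invisible(x)
}

#' Find above-background structure clusters
#'
#' A voxel is "signal" when its intensity exceeds
#' `bg$mean + k_sigma * bg$sd` (raw sensor data is never literally zero,
#' so "non-zero intensity" is operationalized against the background
#' model). Clusters are 26-connected components of signal voxels with at
#' least `min_voxels` members.
#'
#' @param volume a [qc_volume()].
#' @param bg a `background_model` from [estimate_background()].
#' @param k_sigma threshold in background sigmas (>= 0), default 5.
#' @param min_voxels minimum cluster size, default 4.
#' @return A list of `structure_cluster` objects: each a list with
#'   `voxels` (matrix, columns `z`, `y`, `x`, 1-based), `bbox` (2 x 3
#'   matrix of min/max per axis), `n_voxels`, `n_planes_spanned`,
#'   `total_intensity`, `centroid`.
#' @export
find_structure_clusters <- function(volume, bg, k_sigma = 5, min_voxels = 4) {
  stopifnot(inherits(volume, "qc_volume"))
  if (k_sigma < 0) stop("k_sigma must be >= 0")
  v <- volume$data
  thr <- bg$mean + k_sigma * bg$sd
  idx <- which(v > thr, arr.ind = TRUE)   # y, x, z
  if (nrow(idx) == 0L) return(list())
  # union-find over the sparse signal voxels (26-connectivity)
  key <- paste(idx[, 1L], idx[, 2L], idx[, 3L])
  lookup <- stats::setNames(seq_len(nrow(idx)), key)
  parent <- seq_len(nrow(idx))
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (n in seq_len(nrow(idx))) {
    nb_keys <- paste(idx[n, 1L] + offs[, 1L], idx[n, 2L] + offs[, 2L],
                     idx[n, 3L] + offs[, 3L])
    hits <- lookup[nb_keys]
    hits <- hits[!is.na(hits)]
    for (h in hits) {
      ra <- find(n); rb <- find(h)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(nrow(idx)), find, integer(1L))
  out <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) < min_voxels) next
    vox <- cbind(z = idx[members, 3L], y = idx[members, 1L], x = idx[members, 2L])
    inten <- v[idx[members, , drop = FALSE]]
    out[[length(out) + 1L]] <- structure(
      list(voxels = vox,
           bbox = apply(vox, 2L, range),
           n_voxels = nrow(vox),
           n_planes_spanned = length(unique(vox[, "z"])),
           total_intensity = sum(inten),
           centroid = colSums(vox * inten) / sum(inten)),
      class = "structure_cluster")
  }
  out
}

#' @export
print.structure_cluster <- function(x, ...) {
  cat(sprintf("<structure_cluster> %d voxel(s) over %d plane(s), centroid (z,y,x) = (%.1f, %.1f, %.1f)\n",
              x$n_voxels, x$n_planes_spanned,
              x$centroid[["z"]], x$centroid[["y"]], x$centroid[["x"]]))
  invisible(x)
}

#' Normalized cross-correlation map of a template over a search volume
#'
#' Direct (sum-based) 3D NCC: at every placement of `template` inside
#' `search`, the Pearson correlation between the template and the
#' overlapping window. Values lie in \[-1, 1\]; windows with zero variance
#' yield 0 and are flagged in the `"flat"` attribute. NCC is invariant
#' under positive gain and offset of either input.
#'
#' @param template 3D array `[y, x, z]` with nonzero variance, no larger
#'   than `search` along every axis.
#' @param search 3D array `[y, x, z]`.
#' @return 3D array of NCC values with dimension
#'   `dim(search) - dim(template) + 1`.
#' @export
ncc_map <- function(template, search) {
  t_ <- if (is.list(template)) template$data else template
  s_ <- if (is.list(search)) search$data else search
  if (!is.array(t_) || length(dim(t_)) != 3L) t_ <- array(t_, c(dim(t_), 1L))
  if (!is.array(s_) || length(dim(s_)) != 3L) s_ <- array(s_, c(dim(s_), 1L))
  dt <- dim(t_); ds <- dim(s_)
  if (any(dt > ds)) stop("template larger than search volume")
  t0 <- t_ - mean(t_)
  tnorm <- sqrt(sum(t0^2))
  if (tnorm == 0) stop("zero-variance template")
  nd <- ds - dt + 1L
  out <- array(0, nd)
  flat <- array(FALSE, nd)
  nt <- length(t_)
  for (k in seq_len(nd[3L])) for (i in seq_len(nd[2L])) for (j in seq_len(nd[1L])) {
    w <- s_[j:(j + dt[1L] - 1L), i:(i + dt[2L] - 1L), k:(k + dt[3L] - 1L)]
    w0 <- w - sum(w) / nt
    wn <- sqrt(sum(w0^2))
    if (wn == 0) { flat[j, i, k] <- TRUE; next }
    out[j, i, k] <- sum(t0 * w0) / (tnorm * wn)
  }
  attr(out, "flat") <- flat
  out
}

#' Score a structure cluster against a repeated scan
#'
#' Cuts a template around the cluster from scan A (bounding box plus
#' `pad_vox`), correlates it over the corresponding region of scan B
#' extended by `search_halo_vox` (which absorbs small rigid
#' misregistration between consecutive scans), and tests the NCC peak
#' against a Gaussian null fitted to all other NCC values -- excluding the
#' peak's immediate 3^3 neighbourhood so a genuine match does not inflate
#' the null spread. A candidate is flagged when its z-score reaches
#' `threshold_sigma`.
#'
#' @param cluster a `structure_cluster` found in `scan_a`.
#' @param scan_a,scan_b the two [qc_volume()] scans (same shape).
#' @param pad_vox template padding around the cluster bounding box.
#' @param search_halo_vox half-width of the search region beyond the
#'   template footprint.
#' @param threshold_sigma z-score needed to flag a candidate (default 5,
#'   conservative against multiple comparisons across the NCC map).
#' @param robust_null if `TRUE`, fit the null with median/MAD instead of
#'   moments.
#' @return A `candidate_score`: list with `ncc_peak`, `peak_offset_vox`
#'   (peak displacement relative to the nominal registered position, named
#'   `z`, `y`, `x`), `null_mean`, `null_sd`, `z_score`, `flagged`,
#'   `ncc_values` (the null sample, retained for reporting) and `cluster`.
#' @export
score_candidate <- function(cluster, scan_a, scan_b, pad_vox = 2,
                            search_halo_vox = 10, threshold_sigma = 5,
                            robust_null = FALSE) {
  stopifnot(inherits(cluster, "structure_cluster"))
  a <- scan_a$data; b <- scan_b$data
  bb <- cluster$bbox   # rows: min,max; cols z,y,x
  lo <- bb[1L, ] - pad_vox; hi <- bb[2L, ] + pad_vox
  da <- dim(a)[c(3L, 1L, 2L)]   # z, y, x extents
  if (any(lo < 1L) || any(hi > da))
    stop("cluster (with padding) touches the volume border")
  tmpl <- a[lo[["y"]]:hi[["y"]], lo[["x"]]:hi[["x"]], lo[["z"]]:hi[["z"]]]
  slo <- pmax(lo - search_halo_vox, 1L)
  shi <- pmin(hi + search_halo_vox, da)
  srch <- b[slo[["y"]]:shi[["y"]], slo[["x"]]:shi[["x"]], slo[["z"]]:shi[["z"]]]
  m <- ncc_map(tmpl, srch)
  pk <- which(m == max(m), arr.ind = TRUE)[1L, ]
  ncc_peak <- max(m)
  # placement (1,1,1) corresponds to template corner at slo; nominal
  # (registered) placement corner is at lo
  nominal <- lo - slo + 1L
  peak_offset <- c(z = unname(pk[3L] - nominal[["z"]]),
                   y = unname(pk[1L] - nominal[["y"]]),
                   x = unname(pk[2L] - nominal[["x"]]))
  excl <- array(FALSE, dim(m))
  er <- function(c0, n) max(1L, c0 - 1L):min(n, c0 + 1L)
  excl[er(pk[1L], dim(m)[1L]), er(pk[2L], dim(m)[2L]), er(pk[3L], dim(m)[3L])] <- TRUE
  null_vals <- m[!excl & !attr(m, "flat")]
  if (length(null_vals) < 10L) stop("too few NCC values to fit a null")
  null_mean <- if (robust_null) stats::median(null_vals) else mean(null_vals)
  null_sd <- if (robust_null) stats::mad(null_vals) else stats::sd(null_vals)
  if (null_sd == 0) stop("degenerate NCC null (sd = 0)")
  z <- (ncc_peak - null_mean) / null_sd
  structure(list(ncc_peak = ncc_peak, peak_offset_vox = peak_offset,
                 null_mean = null_mean, null_sd = null_sd, z_score = z,
                 flagged = z >= threshold_sigma, ncc_values = null_vals,
                 cluster = cluster),
            class = "candidate_score")
}

#' @export
print.candidate_score <- function(x, ...) {
  cat(sprintf("<candidate_score> peak NCC %.3f, null %.4f +/- %.4f, z = %.1f sigma%s\n",
              x$ncc_peak, x$null_mean, x$null_sd, x$z_score,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Validate candidate structures across a repeated scan pair
#'
#' Clusters found in scan A are scored against scan B and vice versa; a
#' candidate is "confirmed" only when flagged in both directions (found
#' repeatedly in more than one scan), which minimizes the likelihood that
#' it is a noise artifact. Clusters in opposite scans are paired by
#' centroid proximity within the search halo.
#'
#' @param scan_a,scan_b two [qc_volume()] scans of the same specimen,
#'   identical shape.
#' @param bg optional `background_model`; when `NULL` a robust model
#'   (median/MAD) is estimated from scan A, valid for sparse structures.
#' @param k_sigma,min_voxels cluster detection, see
#'   [find_structure_clusters()].
#' @param pad_vox,search_halo_vox,threshold_sigma scoring, see
#'   [score_candidate()].
#' @return A `track_report`: list with `candidates` (data.frame: centroid,
#'   voxel/plane counts, z-scores and flags in both directions,
#'   `confirmed`), `scores_ab`, `scores_ba` (lists of `candidate_score`),
#'   `n_confirmed`, and the parameters used. Has `print` and `summary`
#'   methods.
#' @export
validate_scan_pair <- function(scan_a, scan_b, bg = NULL, k_sigma = 5,
                               min_voxels = 4, pad_vox = 2,
                               search_halo_vox = 10, threshold_sigma = 5) {
  stopifnot(inherits(scan_a, "qc_volume"), inherits(scan_b, "qc_volume"))
  if (!identical(dim(scan_a$data), dim(scan_b$data)))
    stop("scans must have the same shape")
  if (is.null(bg)) bg <- estimate_background(scan_a, robust = TRUE)
  score_all <- function(clusters, from, to) lapply(clusters, function(cl)
    tryCatch(score_candidate(cl, from, to, pad_vox = pad_vox,
                             search_halo_vox = search_halo_vox,
                             threshold_sigma = threshold_sigma),
             error = function(e) NULL))
  cl_a <- find_structure_clusters(scan_a, bg, k_sigma, min_voxels)
  cl_b <- find_structure_clusters(scan_b, bg, k_sigma, min_voxels)
  sc_ab <- score_all(cl_a, scan_a, scan_b)
  sc_ba <- score_all(cl_b, scan_b, scan_a)
  flag_of <- function(s) !is.null(s) && s$flagged
  cents_b <- if (length(cl_b)) t(vapply(cl_b, `[[`, numeric(3L), "centroid")) else
    matrix(numeric(0), 0, 3)
  rows <- lapply(seq_along(cl_a), function(n) {
    cl <- cl_a[[n]]; s <- sc_ab[[n]]
    back_flag <- FALSE; back_z <- NA_real_
    if (nrow(cents_b) > 0) {
      dd <- sqrt(colSums((t(cents_b) - cl$centroid)^2))
      near <- which(dd <= search_halo_vox + cl$n_planes_spanned)
      if (length(near)) {
        back <- near[which.min(dd[near])]
        back_flag <- flag_of(sc_ba[[back]])
        if (!is.null(sc_ba[[back]])) back_z <- sc_ba[[back]]$z_score
      }
    }
    data.frame(z = cl$centroid[["z"]], y = cl$centroid[["y"]],
               x = cl$centroid[["x"]], n_voxels = cl$n_voxels,
               n_planes_spanned = cl$n_planes_spanned,
               ncc_peak = if (is.null(s)) NA_real_ else s$ncc_peak,
               z_score_ab = if (is.null(s)) NA_real_ else s$z_score,
               z_score_ba = back_z,
               flagged_ab = flag_of(s), flagged_ba = back_flag,
               confirmed = flag_of(s) && back_flag)
  })
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
               n_voxels = integer(0), n_planes_spanned = integer(0),
               ncc_peak = numeric(0), z_score_ab = numeric(0),
               z_score_ba = numeric(0), flagged_ab = logical(0),
               flagged_ba = logical(0), confirmed = logical(0))
  structure(list(candidates = candidates, scores_ab = sc_ab, scores_ba = sc_ba,
                 n_clusters_a = length(cl_a), n_clusters_b = length(cl_b),
                 n_confirmed = sum(candidates$confirmed),
                 params = list(k_sigma = k_sigma, min_voxels = min_voxels,
                               pad_vox = pad_vox,
                               search_halo_vox = search_halo_vox,
                               threshold_sigma = threshold_sigma,
                               background = unclass(bg))),
            class = "track_report")
}

#' @export
print.track_report <- function(x, ...) {
  cat("<track_report>\n")
  cat(sprintf("  clusters: %d in scan A, %d in scan B\n",
              x$n_clusters_a, x$n_clusters_b))
  cat(sprintf("  confirmed candidates (flagged both directions): %d\n",
              x$n_confirmed))
  if (nrow(x$candidates) > 0) {
    df <- x$candidates
    df[, c("z", "y", "x", "ncc_peak", "z_score_ab", "z_score_ba")] <-
      round(df[, c("z", "y", "x", "ncc_peak", "z_score_ab", "z_score_ba")], 2)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.track_report <- function(object, ...) {
  print(object)
  invisible(object$candidates)
}

#' @export
report_list.track_report <- function(report) {
  list(n_clusters_a = report$n_clusters_a, n_clusters_b = report$n_clusters_b,
       n_confirmed = report$n_confirmed, params = report$params,
       candidates = report$candidates)
}

#' @export
report_table.track_report <- function(report) report$candidates
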