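#' Generate a parcellation phantom
#'
#' Builds a brain-like digital phantom for exercising the volume-space
#' extraction operations: an ellipsoidal mask partitioned into `n_regions`
#' contiguous labels (nearest-seed growth; 0 = background), piecewise-
#' constant metric volumes with optional Gaussian noise, straight-polyline
#' streamlines between random in-mask points, and a 4D BOLD-like series in
#' which every voxel follows its region's base time course plus noise.
#'
#' All coordinates use a corner-origin world frame with unit voxel size, so
#' the voxel containing point p is `floor(p) + 1` (1-based).
#'
#' @param atlas_shape integer 3-vector, each entry >= 8
#' @param n_regions number of labels (>= 2, at most the mask voxel count)
#' @param seed RNG seed
#' @param region_means per-region metric values (default `1:n_regions`)
#' @param noise_sd SD of voxel noise added to the metric volume
#' @param n_streamlines number of random streamlines
#' @param n_timepoints length of the BOLD-like series (0 = none)
#' @return list with `label` (3D integer array), `metric` (3D array),
#'   `streamlines` (list of k x 3 point matrices), `bold` (4D array or
#'   NULL), `region_means`, `mask`
#' @export
generate_phantom <- function(atlas_shape = c(16L, 16L, 16L),
                             n_regions = 6L,
                             seed = 1L,
                             region_means = seq_len(n_regions),
                             noise_sd = 0,
                             n_streamlines = 0L,
                             n_timepoints = 0L) {
  atlas_shape <- as.integer(atlas_shape)
  if (length(atlas_shape) != 3L || any(atlas_shape < 8L))
    stop("atlas_shape must be a 3-vector with all entries >= 8",
         call. = FALSE)
  if (n_regions < 2L) stop("n_regions must be >= 2", call. = FALSE)
  set.seed(seed)

  idx <- as.matrix(expand.grid(x = seq_len(atlas_shape[1]),
                               y = seq_len(atlas_shape[2]),
                               z = seq_len(atlas_shape[3])))
  ctr <- (atlas_shape + 1) / 2
  semi <- atlas_shape / 2 - 0.5
  d2 <- ((idx[, 1] - ctr[1]) / semi[1])^2 +
        ((idx[, 2] - ctr[2]) / semi[2])^2 +
        ((idx[, 3] - ctr[3]) / semi[3])^2
  in_mask <- d2 <= 1
  if (n_regions > sum(in_mask))
    stop("n_regions exceeds the mask voxel count", call. = FALSE)

  mask_idx <- idx[in_mask, , drop = FALSE]
  seeds <- mask_idx[sample(nrow(mask_idx), n_regions), , drop = FALSE]
  # nearest-seed (Voronoi) labels; ties -> smallest seed index
  dmat <- outer(rowSums(mask_idx^2), rep(1, n_regions)) -
    2 * mask_idx %*% t(seeds) +
    outer(rep(1, nrow(mask_idx)), rowSums(seeds^2))
  lab_vec <- max.col(-dmat, ties.method = "first")

  label <- array(0L, atlas_shape)
  label[in_mask] <- as.integer(lab_vec)

  metric <- array(0, atlas_shape)
  metric[in_mask] <- region_means[lab_vec]
  if (noise_sd > 0)
    metric[in_mask] <- metric[in_mask] + rnorm(sum(in_mask), 0, noise_sd)

  streamlines <- list()
  if (n_streamlines > 0L) {
    for (k in seq_len(n_streamlines)) {
      ends <- mask_idx[sample(nrow(mask_idx), 2L), , drop = FALSE] - 0.5
      npts <- max(2L, ceiling(2 * sqrt(sum((ends[2, ] - ends[1, ])^2))))
      tfrac <- seq(0, 1, length.out = npts)
      streamlines[[k]] <- cbind(ends[1, 1] + tfrac * (ends[2, 1] - ends[1, 1]),
                                ends[1, 2] + tfrac * (ends[2, 2] - ends[1, 2]),
                                ends[1, 3] + tfrac * (ends[2, 3] - ends[1, 3]))
    }
  }

  bold <- NULL
  if (n_timepoints > 0L) {
    base <- matrix(rnorm(n_timepoints * n_regions), n_timepoints, n_regions)
    bold <- array(0, c(atlas_shape, n_timepoints))
    flat <- matrix(0, nrow = prod(atlas_shape), ncol = n_timepoints)
    flat[in_mask, ] <- t(base)[lab_vec, , drop = FALSE]
    if (noise_sd > 0)
      flat[in_mask, ] <- flat[in_mask, ] +
        rnorm(sum(in_mask) * n_timepoints, 0, noise_sd)
    bold <- array(flat, c(atlas_shape, n_timepoints))
  }

  list(label = label, metric = metric, streamlines = streamlines,
       bold = bold, region_means = region_means,
       mask = array(in_mask, atlas_shape))
}
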