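#' Regional mean of a metric volume over an atlas
#'
#' Averages metric values over the voxels of each atlas label — the
#' "weighted volume" reduction used for tissue probability maps (GMV/WMV)
#' and diffusion scalar maps (FA/MD). Background voxels (label 0) are
#' ignored. A label with no voxels yields `NA` and a warning, never a
#' silent zero.
#'
#' @param metric 3D numeric array, voxel-aligned with `atlas`
#' @param atlas 3D integer array of labels (0 = background)
#' @param n_regions number of labels (default `max(atlas)`)
#' @return numeric vector of length `n_regions`
#' @export
region_mean <- function(metric, atlas, n_regions = max(atlas)) {
  if (!identical(dim(metric), dim(atlas)))
    stop("metric and atlas must share the same grid", call. = FALSE)
  lab <- as.integer(atlas)
  val <- as.numeric(metric)
  keep <- lab > 0L
  sums <- rowsum(val[keep], lab[keep])
  counts <- rowsum(rep(1, sum(keep)), lab[keep])
  out <- rep(NA_real_, n_regions)
  present <- as.integer(rownames(sums))
  out[present] <- sums[, 1] / counts[, 1]
  empty <- setdiff(seq_len(n_regions), present)
  if (length(empty))
    warning("regions with no voxels set to NA: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out
}

#' Count streamlines traversing each atlas region
#'
#' A streamline contributes at most once to each region it touches (it may
#' touch several). Point-to-voxel lookup is nearest voxel in a 0-based
#' corner-origin frame: voxel index `floor(p / voxel_size) + 1`. Points
#' outside the grid are ignored; a streamline entirely outside triggers a
#' warning.
#'
#' @param streamlines list of k x 3 point matrices (world coordinates)
#' @param atlas 3D integer label array
#' @param voxel_size numeric 3-vector of voxel dimensions (mm)
#' @param n_regions number of labels (default `max(atlas)`)
#' @return integer count vector of length `n_regions`
#' @export
streamline_counts <- function(streamlines, atlas, voxel_size = c(1, 1, 1),
                              n_regions = max(atlas)) {
  dims <- dim(atlas)
  counts <- integer(n_regions)
  n_lost <- 0L
  for (sl in streamlines) {
    if (!is.matrix(sl) || ncol(sl) != 3L || nrow(sl) < 2L)
      stop("each streamline must be a k x 3 matrix with k >= 2",
           call. = FALSE)
    vox <- floor(sweep(sl, 2, voxel_size, "/")) + 1
    ok <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
          vox[, 2] >= 1 & vox[, 2] <= dims[2] &
          vox[, 3] >= 1 & vox[, 3] <= dims[3]
    if (!any(ok)) {
      n_lost <- n_lost + 1L
      next
    }
    vox <- vox[ok, , drop = FALSE]
    labs <- atlas[cbind(vox[, 1], vox[, 2], vox[, 3])]
    hit <- unique(labs[labs > 0L])
    counts[hit] <- counts[hit] + 1L
  }
  if (n_lost > 0L)
    warning(n_lost, " streamline(s) entirely outside the grid",
            call. = FALSE)
  counts
}

#' Average a 4D BOLD series within atlas regions
#'
#' @param bold 4D array (x, y, z, t), spatially aligned with `atlas`
#' @param atlas 3D integer label array
#' @param n_regions number of labels (default `max(atlas)`)
#' @return T x n_regions matrix of region-mean time series; empty labels
#'   give an NA column with a warning
#' @export
roi_timeseries <- function(bold, atlas, n_regions = max(atlas)) {
  if (length(dim(bold)) != 4L ||
      !identical(dim(bold)[1:3], dim(atlas)))
    stop("bold must be 4D with spatial shape matching atlas", call. = FALSE)
  tdim <- dim(bold)[4]
  flat <- matrix(bold, ncol = tdim)
  lab <- as.integer(atlas)
  keep <- lab > 0L
  sums <- rowsum(flat[keep, , drop = FALSE], lab[keep])
  counts <- as.vector(rowsum(rep(1, sum(keep)), lab[keep]))
  out <- matrix(NA_real_, nrow = tdim, ncol = n_regions)
  present <- as.integer(rownames(sums))
  out[, present] <- t(sums / counts)
  empty <- setdiff(seq_len(n_regions), present)
  if (length(empty))
    warning("regions with no voxels give NA time series: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out
}

#' Pearson functional-connectivity matrix from ROI time series
#'
#' Entry (i, j) is the Pearson correlation of region time courses i and j;
#' the diagonal is exactly 1. A constant (zero-variance) region is an
#' error naming the region, not a silent NaN.
#'
#' @param ts T x R numeric matrix (T >= 3), columns = regions
#' @return symmetric R x R matrix with unit diagonal
#' @export
fc_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(ts))) colnames(ts)[bad] else bad
    stop("zero-variance time series for region(s): ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  m <- cor(ts)
  diag(m) <- 1
  m
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti for the atlas and metric volumes consumed by
#' [region_mean()] and friends.
#'
#' @param path file path (.nii or .nii.gz)
#' @return `read_volume`: a plain numeric array (attributes dropped)
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  a
}

#' @rdname read_volume
#' @param x numeric/integer array to write
#' @param voxel_size voxel dimensions (mm) recorded in the header
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(x, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write streamlines as JSON polylines
#'
#' Interchange format for streamline sets: a JSON object with a
#' `streamlines` field holding a list of k x 3 point arrays (world
#' coordinates, corner-origin frame) and an optional `voxel_size`.
#'
#' @param path file path
#' @export
read_streamlines_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  sls <- lapply(obj$streamlines, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  attr(sls, "voxel_size") <- if (!is.null(obj$voxel_size))
    as.numeric(obj$voxel_size) else c(1, 1, 1)
  sls
}

#' @rdname read_streamlines_json
#' @param streamlines list of k x 3 matrices
#' @param voxel_size voxel dimensions recorded in the file
#' @export
write_streamlines_json <- function(streamlines, path,
                                   voxel_size = c(1, 1, 1)) {
  obj <- list(voxel_size = voxel_size,
              streamlines = lapply(streamlines, unname))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
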