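# Cell segmentation and scalar morphometry on the microglia channel.

#' Segment microglial cells from the Iba1 channel
#'
#' Smooths the channel with a small Gaussian (suppressing single-voxel
#' noise, which would otherwise dominate the threshold statistics at the
#' extreme foreground/background imbalance of sparse cells), applies a
#' global automatic threshold (exact 1-D 2-means over the ROI intensities,
#' [kmeans_threshold()]), labels 26-connected components, and keeps
#' components of at least `min_volume`. The soma centroid of each cell is
#' the interior maximum of the Euclidean distance transform (the deepest
#' point of the mask), a standard proxy for the cell body.
#'
#' @param channel non-negative 3D array (Iba1 intensity).
#' @param grid the [voxel_grid].
#' @param roi optional [roi_bounds()]/[roi_mask()]; default whole stack.
#' @param min_volume minimum cell volume in cubic micrometers (default 50).
#' @param threshold `"kmeans"` or `"manual"`.
#' @param manual_value threshold used when `threshold = "manual"`.
#' @param smooth_sigma Gaussian pre-filter sd in um (default 0.4, below
#'   the process radius; 0 disables).
#' @param min_separation minimum separation between the two intensity
#'   clusters, in units of the pooled within-cluster standard deviation,
#'   for the automatic threshold to count as signal. The 2-means split
#'   of pure unimodal noise separates its halves by only ~1.6 sd
#'   (normalized ~2.7), whereas labeled cells over background separate
#'   by far more; below this the channel is treated as empty rather
#'   than thresholded inside the noise. Default 4.
#' @return List of `cell_mask` objects, each with fields `mask` (logical
#'   array), `soma` (z, y, x in um), `id`, `volume` (um^3). An effectively
#'   empty channel yields an empty list.
#' @export
segment_cells <- function(channel, grid, roi = NULL, min_volume = 50,
                          threshold = c("kmeans", "manual"),
                          manual_value = NA_real_, smooth_sigma = 0.4,
                          min_separation = 4) {
  threshold <- match.arg(threshold)
  if (any(channel < 0)) stop("channel must be non-negative")
  if (is.null(roi)) roi <- roi_full(grid)
  rmask <- roi_as_mask(roi, grid)
  if (!any(rmask)) stop("empty ROI")

  img <- if (smooth_sigma > 0) gauss3d(channel, grid, smooth_sigma)
         else channel
  vals <- img[rmask]
  # the exact 2-means scan on a deterministic stride subsample: at
  # millions of voxels the threshold is unchanged and the sort is cheap
  if (length(vals) > 5e5)
    vals <- vals[seq(1, length(vals), by = ceiling(length(vals) / 5e5))]
  thr <- if (threshold == "manual") manual_value else
    tryCatch(kmeans_threshold(vals),
             error = function(e) NA_real_)  # flat channel: nothing to segment
  if (is.na(thr)) return(list())
  if (threshold == "kmeans") {
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    within_sd <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                        max(length(vals) - 2, 1))
    if ((mean(hi) - mean(lo)) < min_separation * max(within_sd, 1e-12))
      return(list())  # unimodal channel: no cells, only noise
  }

  bin <- img > thr & rmask
  dim(bin) <- grid$shape
  if (!any(bin)) return(list())
  lab <- cpp_label26(bin, grid$shape)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * voxel_volume(grid) >= min_volume)
  if (length(keep) == 0) return(list())

  cells <- vector("list", length(keep))
  for (ci in seq_along(keep)) {
    m <- lab == keep[ci]
    dim(m) <- grid$shape
    soma <- mask_depth_max(m, grid)
    cells[[ci]] <- structure(
      list(mask = m, soma = soma, id = ci,
           volume = sum(m) * voxel_volume(grid)),
      class = "cell_mask")
  }
  cells
}

# location (um) of the interior distance-transform maximum of a mask,
# computed on the cropped bounding box; first (smallest index) tie wins
mask_depth_max <- function(m, grid) {
  w <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, grid$shape)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  depth <- cpp_edt(!sub, dim(sub), grid$voxel_size)
  depth[!sub] <- -1
  best <- arrayInd(which.max(depth), dim(sub))
  drop(voxel_centers(best + rep(lo - 1L, each = nrow(best)), grid))
}

#' Cell volume from a binary mask
#'
#' @param cell a `cell_mask` (or logical 3D array).
#' @param grid the [voxel_grid].
#' @return Volume in cubic micrometers (voxel count times voxel volume).
#' @export
cell_volume <- function(cell, grid) {
  m <- if (inherits(cell, "cell_mask")) cell$mask else cell
  n <- sum(m)
  if (n == 0) stop("empty cell mask")
  n * voxel_volume(grid)
}

#' Microglial density in an ROI
#'
#' Cells are counted by their soma centroid: a cell straddling the ROI
#' border counts if and only if its soma centroid lies inside.
#'
#' @param cells list of `cell_mask` objects.
#' @param roi the [roi_bounds()]/[roi_mask()].
#' @param grid the [voxel_grid].
#' @return List with `count` and `density` (cells per 10^6 um^3).
#' @export
cell_density <- function(cells, roi, grid) {
  n <- if (length(cells) == 0) 0L else {
    somas <- do.call(rbind, lapply(cells, `[[`, "soma"))
    sum(roi_contains(roi, grid, somas))
  }
  v <- roi_volume(roi, grid)
  list(count = n, density = 1e6 * n / v)
}

#' Per-cell morphometry record
#'
#' Convenience wrapper running the full single-cell chain: skeleton, total
#' process length, Sholl profile and summary complexity, mask volume and
#' convex-hull territory.
#'
#' @param cell a `cell_mask` from [segment_cells()].
#' @param grid the [voxel_grid].
#' @param prune_length spur-pruning length (um) for [skeletonize_cell()].
#' @param sholl_step radius step (um) for [sholl_profile()].
#' @details `process_length` excludes the part of the skeleton inside the
#'   soma ball (centered on the soma centroid with radius equal to the
#'   mask depth there): the medial skeleton necessarily runs through the
#'   cell body, but the cell body is not process. `total_length` (the
#'   plain edge-length sum, [total_process_length()]) is reported too.
#' @return A one-row data frame: `cell, process_length, total_length,
#'   complexity, volume, territory` with the Sholl profile attached as
#'   attribute `sholl`.
#' @export
cell_morphometry <- function(cell, grid, prune_length = 1, sholl_step = 1) {
  skel <- skeletonize_cell(cell, grid, prune_length = prune_length)
  sh <- sholl_profile(skel, step = sholl_step)
  terr <- tryCatch(territory_volume(skel),
                   error = function(e) NA_real_)  # near-point cells
  soma_r <- soma_radius_estimate(cell, grid)
  total <- total_process_length(skel)
  inside <- skeleton_length_in_ball(skel, cell$soma, soma_r)
  out <- data.frame(cell = cell$id,
                    process_length = total - inside,
                    total_length = total,
                    complexity = sh$complexity,
                    volume = cell_volume(cell, grid),
                    territory = terr)
  attr(out, "sholl") <- sh
  out
}

# mask depth (um) at the soma centroid: the radius of the largest ball
# centered there that fits inside the mask
soma_radius_estimate <- function(cell, grid) {
  m <- cell$mask
  w <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, grid$shape)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  d <- cpp_edt(!sub, dim(sub), grid$voxel_size)
  idx <- round(phys_to_index(matrix(cell$soma, 1), grid)) - (lo - 1L)
  idx <- pmin(pmax(idx, 1), matrix(as.numeric(dim(sub)), 1))
  d[matrix(as.integer(idx), 1)]
}

# total skeleton edge length falling inside the ball (center, r)
skeleton_length_in_ball <- function(skel, center, r) {
  if (nrow(skel$edges) == 0 || r <= 0) return(0)
  a <- skel$nodes[skel$edges[, 1], , drop = FALSE]
  b <- skel$nodes[skel$edges[, 2], , drop = FALSE]
  d0 <- sweep(a, 2, center)
  e <- b - a
  alpha <- rowSums(e^2)
  beta <- rowSums(d0 * e)
  gam <- rowSums(d0^2) - r^2
  disc <- pmax(beta^2 - alpha * gam, 0)
  sq <- sqrt(disc)
  t1 <- pmin(pmax(ifelse(alpha > 0, (-beta - sq) / alpha, 0), 0), 1)
  t2 <- pmin(pmax(ifelse(alpha > 0, (-beta + sq) / alpha, 0), 0), 1)
  # the [t1, t2] clip of each segment lies inside the sphere
  sum(sqrt(alpha) * pmax(t2 - t1, 0) * (beta^2 - alpha * gam > 0 | gam < 0))
}
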