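# Terminal spot detection: background subtraction, Gaussian filtering,
# scale-normalized 3D Laplacian-of-Gaussian (Mexican hat) at a fixed
# physical spot size, plateau-aware local maxima, and an exact 1-D 2-means
# automatic threshold over the candidate responses.

#' Exact one-dimensional 2-means threshold
#'
#' Computes the optimal two-cluster partition of a numeric sample by an
#' exact scan over all split points of the sorted values (the 1-D 2-means
#' optimum is always an interval split), then returns the midpoint of the
#' two cluster means. Deterministic: no iterative heuristic, ties broken
#' toward the smaller split.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return The threshold (numeric scalar). Values strictly above it belong
#'   to the upper cluster.
#' @examples
#' kmeans_threshold(c(0, 0, 0, 10, 10, 10))  # 5
#' kmeans_threshold(c(1, 2, 9, 10))          # 5.5
#' @export
kmeans_threshold <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 2 || x[1] == x[n])
    stop("degenerate distribution: need at least 2 distinct values")
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  sse_left <- cs2[k] - cs[k]^2 / k
  sse_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(sse_left + sse_right)
  mean_left <- cs[best] / best
  mean_right <- (cs[n] - cs[best]) / (n - best)
  (mean_left + mean_right) / 2
}

#' Spot detection parameters
#'
#' @param diameter physical spot diameter in micrometers. Default 0.8, the
#'   calibrated terminal size used throughout.
#' @param background_sigma standard deviation (um) of the large-scale
#'   Gaussian background estimate; default `5 * diameter`.
#' @param smooth_sigma standard deviation (um) of the Gaussian pre-filter;
#'   default half the spot radius.
#' @param threshold `"kmeans"` for the automatic threshold over candidate
#'   responses, or `"manual"` with `manual_value`.
#' @param manual_value numeric threshold used when `threshold = "manual"`.
#' @return A `detection_params` list.
#' @export
detection_params <- function(diameter = 0.8,
                             background_sigma = NULL,
                             smooth_sigma = NULL,
                             threshold = c("kmeans", "manual"),
                             manual_value = NA_real_) {
  threshold <- match.arg(threshold)
  if (diameter <= 0) stop("spot diameter must be > 0")
  if (is.null(background_sigma)) background_sigma <- 5 * diameter
  if (is.null(smooth_sigma)) smooth_sigma <- (diameter / 2) / 2
  if (background_sigma <= 0 || smooth_sigma <= 0)
    stop("filter scales must be > 0")
  structure(list(diameter = diameter, background_sigma = background_sigma,
                 smooth_sigma = smooth_sigma, threshold = threshold,
                 manual_value = manual_value),
            class = "detection_params")
}

gauss3d <- function(img, grid, sigma_um) {
  sig <- rep(sigma_um, length.out = 3) / grid$voxel_size
  cpp_gaussian_blur(img, grid$shape, sig)
}

# large-scale blur via a mean-pooled pyramid: pool by ~sigma/3 per axis,
# blur the small image, upsample trilinearly. For smooth background
# estimates this is indistinguishable from the direct (much slower) blur.
gauss3d_large <- function(img, grid, sigma_um) {
  sig <- rep(sigma_um, length.out = 3) / grid$voxel_size
  f <- pmax(1L, pmin(as.integer(sig / 3), grid$shape %/% 4L))
  if (all(f == 1L)) return(gauss3d(img, grid, sigma_um))
  small <- cpp_downsample3(img, grid$shape, f)
  small <- cpp_gaussian_blur(small, dim(small), sig / f)
  cpp_upsample3(small, dim(small), grid$shape, f)
}

#' Background subtraction and Gaussian pre-filtering
#'
#' Estimates the background as a large-scale Gaussian blur of the channel,
#' subtracts it (clipping at zero), then applies a small Gaussian smoothing.
#' A constant image maps to all zeros; an isolated peak keeps its location.
#'
#' @param channel non-negative 3D array.
#' @param grid the [voxel_grid].
#' @param params a [detection_params] object.
#' @return Filtered non-negative array of the same shape.
#' @export
preprocess_channel <- function(channel, grid, params = detection_params()) {
  if (any(channel < 0)) stop("channel must be non-negative")
  bg <- gauss3d_large(channel, grid, params$background_sigma)
  x <- pmax(channel - bg, 0)
  dim(x) <- grid$shape
  x <- gauss3d(x, grid, params$smooth_sigma)
  x[x < 0] <- 0
  dim(x) <- grid$shape
  x
}

#' Detect terminal spots with a 3D Mexican-hat filter
#'
#' After preprocessing, computes the scale-normalized Laplacian-of-Gaussian
#' response at sigma = radius / sqrt(3) (the blob-optimal scale for a ball
#' of the stated diameter; sigma is physical, so anisotropic voxels are
#' handled), finds 26-connected local maxima of the response, and retains
#' the maxima whose response clears the automatic [kmeans_threshold()] over
#' all candidate responses (or a manual threshold). Centroids are refined
#' by an intensity-weighted mean over the spot-radius neighborhood. Maxima
#' within one spot radius of the stack border are flagged `edge` and not
#' retained.
#'
#' @param channel non-negative 3D array (the terminal channel).
#' @param grid the [voxel_grid].
#' @param roi optional [roi_bounds()]/[roi_mask()]; detection is restricted
#'   to maxima inside it. Default: whole stack.
#' @param params a [detection_params] object.
#' @param preprocess apply [preprocess_channel()] first (default TRUE).
#' @return A `spot_set`: data frame with columns `id, z, y, x` (um),
#'   `response`, `intensity`, `edge`, `retained`; attributes `diameter`,
#'   `threshold`, `roi_label`.
#' @export
detect_spots <- function(channel, grid, roi = NULL,
                         params = detection_params(), preprocess = TRUE) {
  if (is.null(roi)) roi <- roi_full(grid)
  radius <- params$diameter / 2
  if (any(grid_extent(grid) < params$diameter))
    stop("ROI/stack smaller than one spot diameter")
  img <- if (preprocess) preprocess_channel(channel, grid, params)
         else channel
  sigma <- radius / sqrt(3)
  sm <- gauss3d(img, grid, sigma)
  resp <- -sigma^2 * cpp_laplacian(sm, grid$shape, grid$voxel_size)
  dim(resp) <- grid$shape

  cand <- cpp_local_maxima(resp, grid$shape, .Machine$double.eps)
  empty <- data.frame(id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), response = numeric(),
                      intensity = numeric(), edge = logical(),
                      retained = logical())
  if (length(cand) == 0)
    return(spot_set(empty, params$diameter, NA_real_, roi$label))

  idx <- arrayInd(cand, grid$shape)
  ctr <- voxel_centers(idx, grid)
  inside <- roi_contains(roi, grid, ctr)
  cand <- cand[inside]; idx <- idx[inside, , drop = FALSE]
  ctr <- ctr[inside, , drop = FALSE]
  if (length(cand) == 0)
    return(spot_set(empty, params$diameter, NA_real_, roi$label))

  responses <- resp[cand]
  ext <- grid_extent(grid)
  edge <- ctr[, 1] < radius | ctr[, 2] < radius | ctr[, 3] < radius |
    ctr[, 1] > ext[1] - radius | ctr[, 2] > ext[2] - radius |
    ctr[, 3] > ext[3] - radius

  thr <- if (params$threshold == "manual") {
    params$manual_value
  } else if (length(unique(responses[!edge])) >= 2) {
    kmeans_threshold(responses[!edge])
  } else {
    -Inf  # nothing to separate: keep all interior candidates
  }
  retained <- !edge & responses >= thr

  # intensity-weighted centroid refinement over the spot-radius ball
  # (retained spots only; rejected candidates keep their voxel center)
  off_r <- ceiling(radius / grid$voxel_size)
  offs <- as.matrix(expand.grid(z = -off_r[1]:off_r[1],
                                y = -off_r[2]:off_r[2],
                                x = -off_r[3]:off_r[3]))
  phys <- sweep(offs, 2, grid$voxel_size, "*")
  offs <- offs[rowSums(phys^2) <= radius^2, , drop = FALSE]
  refined <- ctr
  intensity <- img[cbind(idx[, 1], idx[, 2], idx[, 3])]
  for (s in which(retained)) {
    nb <- sweep(offs, 2, idx[s, ], "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= grid$shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid$shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid$shape[3]
    nb <- nb[keep, , drop = FALSE]
    w <- img[nb]
    if (sum(w) > 0)
      refined[s, ] <- colSums(voxel_centers(nb, grid) * w) / sum(w)
  }

  ord <- order(cand)
  df <- data.frame(id = seq_along(cand), z = refined[, 1], y = refined[, 2],
                   x = refined[, 3], response = responses,
                   intensity = intensity, edge = edge,
                   retained = retained)[ord, , drop = FALSE]
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  spot_set(df, params$diameter, thr, roi$label)
}

spot_set <- function(df, diameter, threshold, roi_label) {
  structure(df, class = c("spot_set", "data.frame"),
            diameter = diameter, threshold = threshold,
            roi_label = roi_label)
}

#' Terminal spot density in an ROI
#'
#' @param spots a `spot_set` from [detect_spots()].
#' @param roi the [roi_bounds()]/[roi_mask()] the spots were detected in.
#' @param grid the [voxel_grid].
#' @return List with `count` (retained spots) and `density` (count per
#'   1000 cubic micrometers).
#' @export
spot_density <- function(spots, roi, grid) {
  n <- sum(spots$retained)
  v <- roi_volume(roi, grid)
  list(count = n, density = 1000 * n / v)
}
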