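#' Voxel grid geometry
#'
#' A `voxel_grid` couples voxel counts with physical voxel sizes and fixes
#' the coordinate convention used throughout the package: axis order is
#' (z, y, x), voxel indices are 0-based, and the physical position of voxel
#' (k, j, i) is its center, ((k + 0.5) dz, (j + 0.5) dy, (i + 0.5) dx) in
#' micrometers. Anisotropy (dz different from dy, dx) is permitted.
#'
#' @param shape integer vector (nz, ny, nx), voxel counts per axis.
#' @param voxel_size numeric vector (dz, dy, dx) in micrometers, all > 0.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(50, 64, 64), c(0.1, 0.1, 0.1))
#' grid_extent(g)  # physical extent in um
#' @export
voxel_grid <- function(shape, voxel_size) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3, length(voxel_size) == 3)
  if (any(shape < 1)) stop("voxel counts must be >= 1")
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel sizes must be strictly positive")
  structure(list(shape = shape, voxel_size = voxel_size),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels (z,y,x), %.4g x %.4g x %.4g um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
grid_extent <- function(grid) grid$shape * grid$voxel_size

#' @rdname voxel_grid
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

# physical centers (um) of 1-based array indices idx (n x 3, z,y,x)
voxel_centers <- function(idx, grid) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx - 0.5, 2, grid$voxel_size, "*")
}

# fractional 1-based array index of physical points (n x 3 um)
phys_to_index <- function(pts, grid) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts, 2, grid$voxel_size, "/") + 0.5
}

# quantize doubles to 32-bit float precision (the stack storage precision)
float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  dim(y) <- d
  y
}

#' Multi-channel image stack
#'
#' Container for a 3D multi-channel fluorescence stack: one non-negative
#' intensity array per named channel, all on a shared [voxel_grid], plus
#' animal-level metadata. Channel intensities are stored at 32-bit float
#' precision, matching the on-disk OME-TIFF representation, so that
#' [write_stack()] followed by [read_stack()] is bit-identical.
#'
#' @param channels named list of 3D numeric arrays, all with dim equal to
#'   `grid$shape`; values must be non-negative. Typical names: `"iba1"`
#'   (microglia), `"agrp"` (axon terminals), `"cd68"` (lysosomes),
#'   `"nuclei"`.
#' @param grid a [voxel_grid].
#' @param metadata named list; recognized fields are `animal`, `group`,
#'   `region`, `age` (all optional character scalars).
#' @return An object of class `multichannel_stack`.
#' @export
multichannel_stack <- function(channels, grid, metadata = list()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a non-empty named list")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch) || !identical(as.integer(dim(ch)), grid$shape))
      stop(sprintf("channel '%s' does not match grid shape", nm))
    if (any(ch < 0)) stop(sprintf("channel '%s' has negative intensities", nm))
    channels[[nm]] <- float32(ch)
  }
  structure(list(channels = channels, grid = grid, metadata = metadata),
            class = "multichannel_stack")
}

#' @export
print.multichannel_stack <- function(x, ...) {
  cat(sprintf("multichannel_stack: channels [%s], %d x %d x %d voxels\n",
              paste(names(x$channels), collapse = ", "),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Region of interest on a voxel grid
#'
#' An ROI is either an axis-aligned box, given as 0-based inclusive-start /
#' exclusive-end voxel ranges per axis (z, y, x), or an explicit binary mask
#' on the grid. ROIs are always supplied (from configuration or mask files);
#' they are never inferred from a nuclear stain.
#'
#' @param start,end integer vectors of length 3 (z, y, x), 0-based,
#'   start inclusive and end exclusive.
#' @param label character label (e.g. `"PVHmpd"`, `"ARH"`, `"BSTal"`).
#' @return An object of class `roi`.
#' @export
roi_bounds <- function(start, end, label = "roi") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 3, length(end) == 3)
  if (any(end <= start)) stop("ROI bounds empty: end must exceed start")
  if (any(start < 0)) stop("ROI start must be >= 0")
  structure(list(type = "bounds", start = start, end = end, label = label),
            class = "roi")
}

#' @rdname roi_bounds
#' @param mask logical 3D array matching the grid shape.
#' @export
roi_mask <- function(mask, label = "roi") {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(type = "mask", mask = mask, label = label), class = "roi")
}

#' @rdname roi_bounds
#' @param grid a [voxel_grid] covering the whole stack.
#' @export
roi_full <- function(grid, label = "full") {
  roi_bounds(c(0L, 0L, 0L), grid$shape, label = label)
}

# logical mask of an ROI on a grid, with validation
roi_as_mask <- function(roi, grid) {
  stopifnot(inherits(roi, "roi"), inherits(grid, "voxel_grid"))
  if (roi$type == "mask") {
    if (!identical(as.integer(dim(roi$mask)), grid$shape))
      stop("ROI mask does not match grid shape")
    return(roi$mask)
  }
  if (any(roi$end > grid$shape))
    stop("ROI bounds exceed grid shape")
  m <- array(FALSE, dim = grid$shape)
  m[(roi$start[1] + 1):roi$end[1],
    (roi$start[2] + 1):roi$end[2],
    (roi$start[3] + 1):roi$end[3]] <- TRUE
  m
}

# are physical points (n x 3 um) inside the ROI? A point on a voxel
# boundary belongs to the higher-index voxel (floor convention).
roi_contains <- function(roi, grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  idx <- floor(phys_to_index(pts, grid) - 0.5) + 1  # containing voxel, 1-based
  idx <- pmin(pmax(idx, 1), matrix(grid$shape, nrow(pts), 3, byrow = TRUE))
  inside_grid <- pts >= 0 & sweep(pts, 2, grid_extent(grid), "<=")
  ok <- rowSums(inside_grid) == 3
  m <- roi_as_mask(roi, grid)
  ok & m[cbind(idx[, 1], idx[, 2], idx[, 3])]
}

#' Physical volume of a region of interest
#'
#' @param roi an [roi_bounds()] or [roi_mask()] object.
#' @param grid the [voxel_grid] the ROI lives on.
#' @return Volume in cubic micrometers (included voxel count times voxel
#'   volume). An empty mask yields 0 with a warning.
#' @examples
#' g <- voxel_grid(c(50, 64, 64), c(0.1, 0.1, 0.1))
#' roi_volume(roi_bounds(c(0, 0, 0), c(10, 10, 10)), g)  # 1 um^3
#' @export
roi_volume <- function(roi, grid) {
  m <- roi_as_mask(roi, grid)
  n <- sum(m)
  if (n == 0) warning("ROI contains no voxels")
  n * voxel_volume(grid)
}
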