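# 3D convex hull volume (incremental construction) for cell territory.

#' Volume of the 3D convex hull of a point set
#'
#' Incremental convex hull: starting from an initial non-degenerate
#' tetrahedron, each remaining point outside the current hull removes its
#' visible facets and is reconnected across the horizon edges. The volume
#' is the sum of signed tetrahedra from an interior point over the final
#' facets.
#'
#' @param pts n x 3 numeric matrix of points (any consistent units; volume
#'   comes back in those units cubed).
#' @param tol relative tolerance for visibility/degeneracy tests.
#' @return Hull volume (scalar).
#' @export
convex_hull_volume <- function(pts, tol = 1e-9) {
  pts <- unique(matrix(as.numeric(pts), ncol = 3))
  n <- nrow(pts)
  if (n < 4) stop("degenerate point set: need >= 4 non-coplanar points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))), .Machine$double.eps)
  eps <- tol * scale

  # initial simplex: spread-out extreme points
  i1 <- 1L
  d <- colSums((t(pts) - pts[i1, ])^2)
  i2 <- which.max(d)
  if (sqrt(d[i2]) <= eps) stop("degenerate point set: all points coincide")
  u <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(w[, 2] * u[3] - w[, 3] * u[2],
              w[, 3] * u[1] - w[, 1] * u[3],
              w[, 1] * u[2] - w[, 2] * u[1])
  a <- sqrt(rowSums(cr^2)) / sqrt(sum(u^2))
  i3 <- which.max(a)
  if (a[i3] <= eps) stop("degenerate point set: all points collinear")
  nrm <- crossp(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  h <- abs(as.vector(w %*% nrm))
  i4 <- which.max(h)
  if (h[i4] <= eps) stop("degenerate point set: all points coplanar")

  o <- colMeans(pts[c(i1, i2, i3, i4), ])  # interior reference point
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, function(f) orient_face(f, pts, o)))

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    dists <- face_dist(faces, pts, pts[p, ])
    vis <- dists > eps
    if (!any(vis)) next
    vis_faces <- faces[vis, , drop = FALSE]
    edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)],
                   vis_faces[, c(1, 3)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    newf <- cbind(p, horizon)
    newf <- t(apply(newf, 1, function(f) orient_face(f, pts, o)))
    area2 <- apply(newf, 1, function(f) {
      v <- crossp(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
      sum(v^2)
    })
    newf <- newf[area2 > (eps * scale)^2, , drop = FALSE]
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
  }

  vol <- 0
  for (f in seq_len(nrow(faces))) {
    aa <- pts[faces[f, 1], ] - o
    bb <- pts[faces[f, 2], ] - o
    cc <- pts[faces[f, 3], ] - o
    vol <- vol + sum(crossp(aa, bb) * cc) / 6
  }
  vol
}

crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# orient a face so its normal points away from interior point o
orient_face <- function(f, pts, o) {
  nrm <- crossp(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  if (sum(nrm * (pts[f[1], ] - o)) < 0) f[c(1, 3)] <- f[c(3, 1)]
  f
}

# signed distances of point q from the (outward-oriented) face planes
face_dist <- function(faces, pts, q) {
  vapply(seq_len(nrow(faces)), function(i) {
    f <- faces[i, ]
    nrm <- crossp(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nn <- sqrt(sum(nrm^2))
    if (nn == 0) return(-Inf)
    sum(nrm / nn * (q - pts[f[1], ]))
  }, 0)
}

#' Convex-hull territory of a cell
#'
#' The tissue territory surveyed by a microglial cell, measured as the
#' volume of the convex polyhedron around its skeleton (skeleton nodes
#' plus the soma node), or around its mask surface voxels.
#'
#' @param cell a `skeleton_graph`, a `cell_mask`, or an n x 3 point matrix.
#' @param grid required when `cell` is a mask, to convert voxels to um.
#' @param source `"skeleton"` (default; skeleton nodes + soma) or `"mask"`
#'   (boundary voxel centers of the mask).
#' @return Territory volume in cubic micrometers.
#' @export
territory_volume <- function(cell, grid = NULL,
                             source = c("skeleton", "mask")) {
  source <- match.arg(source)
  if (inherits(cell, "skeleton_graph")) {
    pts <- cell$nodes
  } else if (inherits(cell, "cell_mask") || is.logical(cell)) {
    if (source == "skeleton")
      stop("skeleton source needs a skeleton_graph; pass source = \"mask\"")
    m <- if (inherits(cell, "cell_mask")) cell$mask else cell
    if (is.null(grid)) stop("grid required for a mask input")
    pts <- voxel_centers(which(boundary_voxels(m), arr.ind = TRUE), grid)
  } else {
    pts <- matrix(as.numeric(cell), ncol = 3)
  }
  convex_hull_volume(pts)
}

# mask voxels with at least one 6-neighbor outside the mask (array borders
# count as background)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  shifted_all <- array(TRUE, d)
  inner <- mask
  pad <- function(a, axis, dir) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (dir > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
    else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (axis in 1:3) for (dir in c(-1, 1))
    shifted_all <- shifted_all & pad(mask, axis, dir)
  mask & !shifted_all
}
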