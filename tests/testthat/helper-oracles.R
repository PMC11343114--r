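# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths. They share no code with the package.

# Sholl crossings by dense sampling of each edge: count sign changes of
# (distance from root - r) along the sampled segment.
bf_sholl_counts <- function(skel, radii, n_samples = 2001) {
  center <- skel$nodes[skel$root, ]
  ts <- seq(0, 1, length.out = n_samples)
  total <- integer(length(radii))
  for (e in seq_len(nrow(skel$edges))) {
    a <- skel$nodes[skel$edges[e, 1], ]
    b <- skel$nodes[skel$edges[e, 2], ]
    p <- outer(ts, b - a) + matrix(a, length(ts), 3, byrow = TRUE)
    dist_t <- sqrt(rowSums(sweep(p, 2, center)^2))
    for (ri in seq_along(radii)) {
      d <- dist_t - radii[ri]
      total[ri] <- total[ri] + sum(diff(sign(d)) != 0 & sign(d[-1]) != 0)
    }
  }
  as.integer(total)
}

# Convex hull volume by exhaustive facet enumeration (general-position
# points): a triple is a hull facet iff all points lie on one side of its
# plane; the volume is the sum of signed tetrahedra against the centroid.
bf_hull_volume <- function(pts) {
  pts <- unique(matrix(as.numeric(pts), ncol = 3))
  n <- nrow(pts)
  o <- colMeans(pts)
  vol <- 0
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  tol <- 1e-9 * scale
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- cross3(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    s <- as.vector(sweep(pts, 2, pts[i, ]) %*% nrm) / sqrt(sum(nrm^2))
    if (all(s <= tol) || all(s >= -tol)) {
      # tet (o, i, j, k): o is interior, so |det|/6 is its volume
      vol <- vol + abs(det(rbind(pts[i, ] - o, pts[j, ] - o,
                                 pts[k, ] - o))) / 6
    }
  }
  vol
}

# Exhaustive 1-D 2-means: try every split of the sorted values.
bf_kmeans_threshold <- function(x) {
  x <- sort(x)
  n <- length(x)
  best_sse <- Inf; best_thr <- NA_real_
  for (k in 1:(n - 1)) {
    l <- x[1:k]; r <- x[(k + 1):n]
    sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_thr <- (mean(l) + mean(r)) / 2
    }
  }
  best_thr
}

# Brute-force signed distance to the nearest boundary voxel center
# (boundary = mask voxel with a face neighbor outside), positive outside.
bf_signed_distance <- function(mask, grid) {
  d <- dim(mask)
  is_bnd <- function(k, j, i) {
    nb <- rbind(c(k - 1, j, i), c(k + 1, j, i), c(k, j - 1, i),
                c(k, j + 1, i), c(k, j, i - 1), c(k, j, i + 1))
    any(apply(nb, 1, function(v)
      any(v < 1) || v[1] > d[1] || v[2] > d[2] || v[3] > d[3] ||
        !mask[v[1], v[2], v[3]]))
  }
  w <- which(mask, arr.ind = TRUE)
  bnd <- w[apply(w, 1, function(v) is_bnd(v[1], v[2], v[3])), , drop = FALSE]
  bctr <- sweep(bnd - 0.5, 2, grid$voxel_size, "*")
  all_idx <- as.matrix(expand.grid(k = seq_len(d[1]), j = seq_len(d[2]),
                                   i = seq_len(d[3])))
  ctr <- sweep(all_idx - 0.5, 2, grid$voxel_size, "*")
  out <- numeric(nrow(ctr))
  chunk <- 2000
  for (s in seq(1, nrow(ctr), by = chunk)) {
    e <- min(s + chunk - 1, nrow(ctr))
    # squared distances chunk x boundary
    dm <- outer(rowSums(ctr[s:e, , drop = FALSE]^2), rowSums(bctr^2), "+") -
      2 * ctr[s:e, , drop = FALSE] %*% t(bctr)
    out[s:e] <- sqrt(pmax(apply(dm, 1, min), 0))
  }
  sgn <- ifelse(mask[all_idx], -1, 1)
  array(sgn * out, d)
}

# Expected branch count of the depth-capped binary branching law with
# fixed segment length L: recursion over expected segments per depth.
bf_expected_branches <- function(n_primary, branch_rate, L, max_depth) {
  p <- 1 - exp(-branch_rate * L)
  n_d <- 1
  branches <- 0
  for (d in seq_len(max_depth)) {
    if (d < max_depth) branches <- branches + p * n_d
    n_d <- 2 * p * n_d
  }
  n_primary * branches
}

# greedy one-to-one matching of detections to truth within match_radius
match_spots <- function(truth, det, match_radius = 0.4) {
  if (nrow(det) == 0 || nrow(truth) == 0)
    return(list(tp = 0L, recall = 0, precision = if (nrow(det)) 0 else NA))
  dm <- as.matrix(dist(rbind(as.matrix(truth), as.matrix(det))))
  dm <- dm[seq_len(nrow(truth)), nrow(truth) + seq_len(nrow(det)),
           drop = FALSE]
  tp <- 0L
  while (TRUE) {
    m <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = FALSE]
    if (dm[m] > match_radius) break
    tp <- tp + 1L
    dm[m[1], ] <- Inf
    dm[, m[2]] <- Inf
    if (all(!is.finite(dm))) break
  }
  list(tp = tp, recall = tp / nrow(truth), precision = tp / nrow(det))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# random connected skeleton tree with n nodes in a box of side `side` um
random_tree <- function(n, side = 20, seed = 1) {
  set.seed(seed)
  nodes <- matrix(runif(3 * n, 0, side), n, 3)
  # parent of node i is a uniform draw among nodes 1..(i-1)
  parents <- vapply(2:n, function(i) sample.int(i - 1, 1), 1L)
  gliamorph:::skeleton_graph(nodes, cbind(parents, 2:n), root = 1L)
}
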