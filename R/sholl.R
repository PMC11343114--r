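# Sholl analysis on skeleton graphs: concentric spheres around the soma,
# counting every crossing of a skeleton edge with each sphere.

#' Sholl profile of a skeleton
#'
#' For each radius r, counts the intersections of skeleton edges with the
#' sphere of radius r centered on the root (soma) node. Each edge is
#' treated as a line segment; an edge crossing the sphere k times
#' contributes k (computed exactly from the quadratic along the segment,
#' so an edge that dips inside and back out counts twice). The summary
#' branching complexity is the sum of counts over all radii — every
#' process-sphere contact counts as one level of branching. The full
#' profile is always returned alongside the summary.
#'
#' @param skeleton a `skeleton_graph` with a designated root.
#' @param radii strictly increasing positive radii (um). Default:
#'   `step, 2*step, ...` up to the maximal node distance from the root.
#' @param step radius step (um) for the default radii; default 1.
#' @return A `sholl_profile`: list with `radii`, `counts` (integers) and
#'   `complexity` (sum of counts).
#' @export
sholl_profile <- function(skeleton, radii = NULL, step = 1) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  center <- skeleton$nodes[skeleton$root, ]
  if (is.null(radii)) {
    maxd <- if (nrow(skeleton$nodes)) {
      sqrt(max(colSums((t(skeleton$nodes) - center)^2)))
    } else 0
    radii <- seq(step, max(step, maxd), by = step)
  }
  radii <- as.numeric(radii)
  if (length(radii) == 0) stop("no radii given")
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing")

  counts <- integer(length(radii))
  if (nrow(skeleton$edges)) {
    a <- skeleton$nodes[skeleton$edges[, 1], , drop = FALSE]
    b <- skeleton$nodes[skeleton$edges[, 2], , drop = FALSE]
    d0 <- sweep(a, 2, center)
    e <- b - a
    alpha <- rowSums(e^2)
    beta <- rowSums(d0 * e)
    gamma0 <- rowSums(d0^2)
    for (ri in seq_along(radii)) {
      gam <- gamma0 - radii[ri]^2
      disc <- beta^2 - alpha * gam
      ok <- disc >= 0 & alpha > 0
      sq <- sqrt(pmax(disc, 0))
      t1 <- (-beta - sq) / alpha
      t2 <- (-beta + sq) / alpha
      n <- (ok & t1 >= 0 & t1 <= 1) + (ok & disc > 0 & t2 >= 0 & t2 <= 1)
      counts[ri] <- sum(n)
    }
  }
  structure(list(radii = radii, counts = as.integer(counts),
                 complexity = as.integer(sum(counts))),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("sholl_profile: %d radii (%.3g..%.3g um), complexity %d\n",
              length(x$radii), min(x$radii), max(x$radii), x$complexity))
  invisible(x)
}
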