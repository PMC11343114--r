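# Segmentation, skeletons, Sholl profiles, convex hulls and densities.

make_grid <- function(n = 64, h = 0.25) voxel_grid(rep(n, 3), rep(h, 3))

# capsule rasterizer shortcut for fixtures
tube_mask <- function(grid, p0, p1, r) {
  m <- array(0L, grid$shape)
  gliamorph:::cpp_add_capsule(m, grid$shape, grid$voxel_size, p0, p1, r)
  array(m == 1L, grid$shape)
}

test_that("three separated cells segment with Dice > 0.7 each", {
  g <- voxel_grid(c(72, 144, 144), c(0.4, 0.4, 0.4))
  ext <- grid_extent(g)
  somas <- rbind(c(ext[1] / 2, 12, 12), c(ext[1] / 2, 12, 45),
                 c(ext[1] / 2, 45, 28))
  cells_true <- lapply(1:3, function(i) {
    mdl <- glia_model(soma_center = somas[i, ], mean_segment = 3,
                      max_depth = 2, n_primary = 3)
    grow_glia(mdl, seed = 100 + i, grid = g)
  })
  sc <- render_scene(cells_true, NULL, g,
                     noise = noise_model(read_sd = 2, photon_scale = 1),
                     seed = 9)
  found <- segment_cells(sc$stack$channels$iba1, g)
  expect_length(found, 3)
  for (ct in cells_true) {
    dices <- vapply(found, function(f) dice_coef(f$mask, ct$mask), 0)
    expect_gt(max(dices), 0.7)
  }
})

test_that("flat or sub-volume channels segment to nothing", {
  g <- make_grid(32)
  expect_equal(segment_cells(array(0, g$shape), g), list())
  # a bright blob far below the minimum volume is filtered out
  m <- tube_mask(g, c(4, 4, 4), c(4, 4, 5), 0.5) * 100
  expect_equal(segment_cells(array(m, g$shape), g, min_volume = 50), list())
  expect_error(segment_cells(array(0, g$shape), g,
                             roi = roi_mask(array(FALSE, g$shape))),
               "empty ROI")
})

test_that("skeleton length of a straight tube matches its axial length", {
  g <- voxel_grid(c(24, 24, 120), c(0.25, 0.25, 0.25))
  m <- tube_mask(g, c(3, 3, 5), c(3, 3, 25), 0.5)
  sk <- skeletonize_cell(m, g, soma = c(3, 3, 5), prune_length = 1)
  expect_lt(abs(total_process_length(sk) - 20) / 20, 0.1)
})

test_that("a ball skeletonizes to a near-point, tiny masks error", {
  g <- make_grid(40, 0.2)
  m <- tube_mask(g, c(4, 4, 4), c(4, 4, 4), 1.5)  # ball r = 1.5 um
  sk <- skeletonize_cell(m, g, soma = c(4, 4, 4))
  expect_lt(total_process_length(sk), 1.5)
  one <- array(FALSE, g$shape); one[3, 3, 3] <- TRUE
  expect_error(skeletonize_cell(one, g, soma = c(0.5, 0.5, 0.5)),
               "< 2 voxels")
})

test_that("a Y-shaped tube yields exactly one degree-3 branch node", {
  g <- voxel_grid(c(32, 96, 96), c(0.25, 0.25, 0.25))
  z <- 4
  m <- tube_mask(g, c(z, 12, 2), c(z, 12, 12), 0.5) |
    tube_mask(g, c(z, 12, 12), c(z, 6, 20), 0.5) |
    tube_mask(g, c(z, 12, 12), c(z, 18, 20), 0.5)
  sk <- skeletonize_cell(m, g, soma = c(z, 12, 2), prune_length = 1)
  deg <- tabulate(c(sk$edges), nbins = nrow(sk$nodes))
  expect_equal(sum(deg >= 3), 1)
  expect_equal(max(deg), 3)
})

test_that("total_process_length sums Euclidean edge lengths", {
  sk <- gliamorph:::skeleton_graph(rbind(c(0, 0, 0), c(0, 3, 4)),
                                   matrix(c(1L, 2L), 1), root = 1L)
  expect_equal(total_process_length(sk), 5)
  empty <- gliamorph:::skeleton_graph(matrix(c(0, 0, 0), 1),
                                      matrix(integer(), 0, 2), root = 1L)
  expect_equal(total_process_length(empty), 0)
  tr <- random_tree(51, seed = 8)
  manual <- sum(sqrt(rowSums((tr$nodes[tr$edges[, 1], ] -
                                tr$nodes[tr$edges[, 2], ])^2)))
  expect_equal(total_process_length(tr), manual)
})

test_that("Sholl counts match simple geometry", {
  # straight 20 um process from the root
  sk <- gliamorph:::skeleton_graph(rbind(c(0, 0, 0), c(0, 0, 20)),
                                   matrix(c(1L, 2L), 1), root = 1L)
  p <- sholl_profile(sk, radii = c(5, 10, 15, 25))
  expect_equal(p$counts, c(1L, 1L, 1L, 0L))
  expect_equal(p$complexity, 3L)

  # 10 um trunk then two branches out to 20 um
  sk2 <- gliamorph:::skeleton_graph(
    rbind(c(0, 0, 0), c(0, 0, 10), c(0, 7, 17), c(0, -7, 17)),
    rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)), root = 1L)
  p2 <- sholl_profile(sk2, radii = c(5, 15))
  expect_equal(p2$counts, c(1L, 2L))

  expect_error(sholl_profile(sk, radii = numeric(0)), "no radii")
  expect_error(sholl_profile(sk, radii = c(5, 5)), "increasing")
})

test_that("Sholl profiles match the dense-sampling oracle on random trees", {
  for (s in 1:12) {
    tr <- random_tree(sample(10:60, 1), side = 15, seed = 200 + s)
    radii <- seq(0.5, 26, by = 0.5)
    p <- sholl_profile(tr, radii = radii)
    expect_equal(p$counts, bf_sholl_counts(tr, radii))
    expect_equal(p$counts[length(radii)], 0L)  # beyond max node distance
  }
})

test_that("adding an edge never decreases length or Sholl complexity", {
  set.seed(31)
  for (i in 1:10) {
    tr <- random_tree(20, seed = 300 + i)
    radii <- seq(1, 30, by = 1)
    base_len <- total_process_length(tr)
    base_cx <- sholl_profile(tr, radii = radii)$complexity
    grown <- gliamorph:::skeleton_graph(
      rbind(tr$nodes, runif(3, 0, 15)),
      rbind(tr$edges, c(sample.int(nrow(tr$nodes), 1),
                        nrow(tr$nodes) + 1L)),
      root = tr$root)
    expect_gte(total_process_length(grown), base_len)
    expect_gte(sholl_profile(grown, radii = radii)$complexity, base_cx)
  }
})

test_that("cell volume is exact voxel arithmetic and matches a digitized ball", {
  g <- voxel_grid(c(100, 100, 100), c(0.1, 0.1, 0.1))
  m <- array(FALSE, g$shape); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(cell_volume(m, g), 1.0)
  expect_error(cell_volume(array(FALSE, g$shape), g), "empty")
  ball <- tube_mask(g, c(5, 5, 5), c(5, 5, 5), 3)
  expect_lt(abs(cell_volume(ball, g) - 36 * pi) / (36 * pi), 0.05)
})

test_that("hull volumes: cube, tetrahedron, oracle agreement, rotation", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  expect_equal(convex_hull_volume(cube), 1000)
  tet <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0), c(0, 0, 6))
  expect_equal(convex_hull_volume(tet), 36)
  set.seed(99)
  for (i in 1:15) {
    pts <- matrix(rnorm(3 * sample(10:60, 1)), ncol = 3)
    v <- convex_hull_volume(pts)
    expect_equal(v, bf_hull_volume(pts), tolerance = 1e-9)
    # rigid rotation invariance
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(convex_hull_volume(pts %*% q), v, tolerance = 1e-6)
  }
  expect_error(convex_hull_volume(rbind(c(0, 0, 0), c(1, 1, 1))),
               "degenerate")
  expect_error(convex_hull_volume(cbind(runif(10), runif(10), 0)),
               "coplanar")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(convex_hull_volume(line), "collinear")
})

test_that("territory volume of a skeleton contains its points", {
  tr <- random_tree(40, seed = 17)
  v <- territory_volume(tr)
  expect_gt(v, 0)
  expect_equal(v, convex_hull_volume(tr$nodes))
})

test_that("cell density counts soma centroids inside the ROI", {
  g <- voxel_grid(c(100, 100, 100), c(1, 1, 1))  # 1e6 um^3
  mk <- function(soma) structure(list(mask = NULL, soma = soma, id = 1L),
                                 class = "cell_mask")
  cells <- lapply(list(c(5, 5, 5), c(50, 50, 50), c(20, 80, 30),
                       c(99, 99, 99), c(1, 50, 70)), mk)
  d <- cell_density(cells, roi_full(g), g)
  expect_equal(d$count, 5L)
  expect_equal(d$density, 5)
  expect_equal(cell_density(list(), roi_full(g), g)$count, 0L)
  # border rule: soma inside counts, soma outside does not
  half <- roi_bounds(c(0, 0, 0), c(100, 100, 50))
  d2 <- cell_density(cells, half, g)
  expect_equal(d2$count, 2L)  # somas with x < 50 um: (5,5,5) and (20,80,30)
})
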