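test_that("exact 2-means threshold matches hand cases and errors on flat input", {
  expect_equal(kmeans_threshold(c(0, 0, 0, 10, 10, 10)), 5)
  expect_equal(kmeans_threshold(c(1, 2, 9, 10)), (1.5 + 9.5) / 2)
  expect_error(kmeans_threshold(c(3, 3, 3)), "degenerate")
  expect_error(kmeans_threshold(7), "degenerate")
})

test_that("2-means threshold equals exhaustive split enumeration", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:200, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                c(rnorm(n %/% 2 + 1), rnorm(n %/% 2 + 1, 8)),
                rexp(n) * 10)
    expect_equal(kmeans_threshold(x), bf_kmeans_threshold(x),
                 tolerance = 1e-12)
  }
})

test_that("2-means threshold is affine-equivariant", {
  set.seed(3)
  x <- c(rnorm(40), rnorm(30, 6))
  thr <- kmeans_threshold(x)
  expect_equal(kmeans_threshold(3 * x + 2), 3 * thr + 2)
  # negative scale flips the clusters but the midpoint maps along
  expect_equal(kmeans_threshold(-2 * x + 1), -2 * thr + 1)
})

test_that("preprocessing removes flat background and keeps peak locations", {
  g <- voxel_grid(c(32, 32, 32), c(0.2, 0.2, 0.2))
  flat <- array(7, g$shape)
  out <- preprocess_channel(flat, g)
  expect_true(all(abs(out) < 1e-9))

  img <- array(0, g$shape)
  img[16, 16, 16] <- 100
  out <- preprocess_channel(img, g)
  expect_equal(arrayInd(which.max(out), g$shape)[1, ], c(16L, 16L, 16L))
})

test_that("a ramp background does not displace a detected spot by a voxel", {
  g <- voxel_grid(c(32, 32, 32), c(0.2, 0.2, 0.2))
  ctr <- matrix(c(3.21, 3.25, 3.33), 1)
  sc <- render_scene(list(), spot_model(intensity = 100), g,
                     noise = noise_model(0, 0), seed = 1,
                     spot_centers = ctr)
  img <- sc$stack$channels$agrp
  ramp <- img + rep(seq(0, 30, length.out = 32), each = 32 * 32)
  dim(ramp) <- g$shape
  s1 <- detect_spots(img, g)
  s2 <- detect_spots(ramp, g)
  p1 <- unlist(s1[which(s1$retained)[1], c("z", "y", "x")])
  p2 <- unlist(s2[which(s2$retained)[1], c("z", "y", "x")])
  expect_lt(sqrt(sum((p1 - p2)^2)), 0.2)  # < 1 voxel
})

test_that("a single rendered spot is found once, sub-voxel accurately", {
  g <- voxel_grid(c(48, 48, 48), c(0.2, 0.2, 0.2))
  sm <- spot_model(density = 0, intensity = 100)
  ctr <- matrix(c(4.83, 4.71, 4.95), 1)
  sc <- render_scene(list(), sm, g, noise = noise_model(0, 0), seed = 1,
                     spot_centers = ctr)
  sp <- detect_spots(sc$stack$channels$agrp, g)
  expect_equal(sum(sp$retained), 1)
  got <- unlist(sp[sp$retained, c("z", "y", "x")])
  expect_lt(sqrt(sum((got - ctr)^2)), 0.5 * 0.2)
})

test_that("a blank noiseless volume yields no spots", {
  g <- voxel_grid(c(24, 24, 24), c(0.2, 0.2, 0.2))
  sp <- detect_spots(array(0, g$shape), g)
  expect_equal(nrow(sp), 0)
  expect_equal(spot_density(sp, roi_full(g), g)$count, 0)
})

test_that("spot count is monotone non-increasing in the manual threshold", {
  g <- voxel_grid(c(48, 48, 48), c(0.2, 0.2, 0.2))
  set.seed(5)
  ctrs <- sample_separated_points(12, rep(1.2, 3), rep(8.4, 3), 1.6)
  sc <- render_scene(list(), spot_model(intensity = 100), g,
                     noise = noise_model(read_sd = 8, photon_scale = 0),
                     seed = 2, spot_centers = ctrs)
  counts <- vapply(c(0.1, 1, 5, 20, 60), function(th) {
    sp <- detect_spots(sc$stack$channels$agrp, g,
                       params = detection_params(threshold = "manual",
                                                 manual_value = th))
    sum(sp$retained)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is equivariant under whole-voxel translations", {
  g <- voxel_grid(c(40, 40, 40), c(0.2, 0.2, 0.2))
  img <- array(0, g$shape)
  set.seed(11)
  ctrs <- sample_separated_points(5, rep(2, 3), rep(5, 3), 1.6)
  sc <- render_scene(list(), spot_model(intensity = 100), g,
                     noise = noise_model(0, 0), seed = 3,
                     spot_centers = ctrs)
  img <- sc$stack$channels$agrp
  shift <- c(3L, 2L, 1L)
  img2 <- array(0, g$shape)
  img2[(1 + shift[1]):40, (1 + shift[2]):40, (1 + shift[3]):40] <-
    img[1:(40 - shift[1]), 1:(40 - shift[2]), 1:(40 - shift[3])]
  s1 <- detect_spots(img, g)
  s2 <- detect_spots(img2, g)
  expect_equal(sum(s1$retained), sum(s2$retained))
  a <- as.matrix(s1[s1$retained, c("z", "y", "x")])
  b <- as.matrix(s2[s2$retained, c("z", "y", "x")])
  a <- a[order(a[, 1], a[, 2], a[, 3]), , drop = FALSE]
  b <- b[order(b[, 1], b[, 2], b[, 3]), , drop = FALSE]
  # equivariant up to a small numerical tolerance: the block-pyramid
  # background estimate is grid-aligned, so refined centroids can move
  # by a tiny fraction of a voxel
  expect_lt(max(abs((b - a) -
                      matrix(shift * g$voxel_size, nrow(a), 3,
                             byrow = TRUE))), 0.05)
})

test_that("spot density normalizes to counts per 1000 um^3", {
  g <- voxel_grid(c(100, 100, 100), c(0.1, 0.1, 0.1))  # 1000 um^3
  df <- data.frame(id = 1:20, z = runif(20, 0, 10), y = runif(20, 0, 10),
                   x = runif(20, 0, 10), response = 1, intensity = 1,
                   edge = FALSE, retained = TRUE)
  sp <- gliamorph:::spot_set(df, 0.8, 0.5, "full")
  expect_equal(spot_density(sp, roi_full(g), g)$density, 20)
})
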