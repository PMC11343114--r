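# Signed distances, the contact/engulfment rule, CD68 volume and summaries.

ball_mask <- function(grid, center, r) {
  m <- array(0L, grid$shape)
  gliamorph:::cpp_add_capsule(m, grid$shape, grid$voxel_size, center,
                              center, r)
  array(m == 1L, grid$shape)
}

test_that("signed distance around a ball matches sphere geometry", {
  g <- voxel_grid(c(120, 120, 120), c(0.1, 0.1, 0.1))
  ctr <- c(6, 6, 6)
  m <- ball_mask(g, ctr, 5)
  f <- signed_distance(list(m), g)
  at <- function(p) gliamorph:::interp_field(f, matrix(p, 1))
  expect_equal(at(ctr + c(6, 0, 0)), 1.0, tolerance = 0.1)
  expect_equal(at(ctr + c(0, 4, 0)), -1.0, tolerance = 0.1)
  expect_error(signed_distance(list(), g), "no cell masks")
})

test_that("signed distances agree with brute-force nearest-boundary search", {
  set.seed(21)
  for (i in 1:5) {
    shape <- c(sample(8:16, 1), sample(8:16, 1), sample(8:16, 1))
    g <- voxel_grid(shape, runif(3, 0.1, 0.3))
    m <- array(FALSE, shape)
    # a couple of random blobs
    for (b in 1:2) {
      c0 <- runif(3) * grid_extent(g)
      mm <- array(0L, shape)
      gliamorph:::cpp_add_capsule(mm, shape, g$voxel_size, c0, c0,
                                  runif(1, 0.3, 1))
      m <- m | (mm == 1L)
    }
    if (!any(m)) next
    dim(m) <- shape
    f <- signed_distance(list(m), g)
    bf <- bf_signed_distance(m, g)
    half_diag <- sqrt(sum(g$voxel_size^2)) / 2
    expect_lt(max(abs(f$distance - bf)), half_diag + 1e-9)
  }
})

test_that("the distance rule classifies the canonical cases", {
  d <- c(0.9, -0.3, 2.0, -0.8)
  shell <- classify_distance(d, mode = "shell")
  expect_equal(as.character(shell$class),
               c("contact", "engulfed", "free", "contact"))
  expect_equal(shell$deep_interior, c(FALSE, FALSE, FALSE, TRUE))
  full <- classify_distance(d, mode = "full_interior")
  expect_equal(as.character(full$class),
               c("contact", "engulfed", "free", "engulfed"))
  # just-inside centroid that is not engulfed still counts as contact
  expect_equal(as.character(classify_distance(-0.7, mode = "shell")$class),
               "contact")
  expect_error(classify_distance(c(1, NA)), "NaN/NA")
})

test_that("every spot gets exactly one class and counts partition", {
  g <- voxel_grid(c(60, 60, 60), c(0.15, 0.15, 0.15))
  m <- ball_mask(g, c(4.5, 4.5, 4.5), 2)
  f <- signed_distance(list(m), g)
  set.seed(4)
  df <- data.frame(id = 1:50, z = runif(50, 0.5, 8.5),
                   y = runif(50, 0.5, 8.5), x = runif(50, 0.5, 8.5),
                   response = 1, intensity = 1, edge = FALSE,
                   retained = TRUE)
  sp <- gliamorph:::spot_set(df, 0.8, 0.5, "roi")
  rec <- classify_spots(sp, f)
  expect_equal(nrow(rec), 50)
  expect_equal(sum(table(rec$class)), 50)
  # raising contact_max never decreases contact + engulfed
  counts <- vapply(c(0.5, 1, 2, 4), function(cm) {
    r <- classify_spots(sp, f, contact_max = cm)
    sum(r$class != "free")
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("classification from measured fields reproduces planted truth", {
  g <- voxel_grid(c(100, 100, 100), c(0.1, 0.1, 0.1))
  mdl <- glia_model(soma_center = grid_extent(g) / 2, soma_radius = 1.5,
                    n_primary = 3, mean_segment = 2.5, max_depth = 2,
                    process_radius = 0.5, branch_rate = 0.3)
  cell <- grow_glia(mdl, seed = 77, grid = g)
  sc <- render_scene(list(cell), spot_model(density = 0.05,
                                            frac_contact = 0.3,
                                            frac_engulfed = 0.3),
                     g, noise = noise_model(0, 0), seed = 77)
  truth <- sc$truth$spots
  f <- signed_distance(list(cell$mask), g)
  rec <- classify_spots(truth, f)
  expect_equal(as.character(rec$class), truth$class)
})

test_that("CD68 volume is masked, thresholded and bounded by cell volume", {
  g <- voxel_grid(c(80, 80, 80), c(0.15, 0.15, 0.15))
  cellm <- ball_mask(g, c(6, 6, 6), 3)
  cell <- structure(list(mask = cellm, soma = c(6, 6, 6), id = 1L),
                    class = "cell_mask")
  # all-zero channel: zero volume
  z <- cd68_volume(array(0, g$shape), list(cell), g)
  expect_equal(z$per_cell$cd68_volume, 0)
  expect_error(cd68_volume(array(0, g$shape), list(), g), "no cell masks")

  # planted puncta inside the cell, plus a decoy outside every mask
  pm <- ball_mask(g, c(6, 6, 6), 0.8) | ball_mask(g, c(5, 7, 6), 0.6)
  outside <- ball_mask(g, c(2, 2, 2), 1)
  chan <- (pm | outside) * 100 + 0
  dim(chan) <- g$shape
  truth_vol <- sum(pm & cellm) * voxel_volume(g)
  got <- cd68_volume(chan, list(cell), g)
  expect_equal(got$per_cell$cd68_volume, truth_vol, tolerance = 0.1)
  expect_lte(got$per_cell$cd68_volume, cell_volume(cell, g))

  # noisy version still within 10 % of planted volume
  set.seed(12)
  noisy <- chan + array(abs(rnorm(length(chan), 0, 3)), g$shape)
  got2 <- cd68_volume(noisy, list(cell), g)
  expect_equal(got2$per_cell$cd68_volume, truth_vol,
               tolerance = 0.1 * truth_vol)
})

test_that("engulfment summaries aggregate counts, density and fraction", {
  g <- voxel_grid(c(100, 100, 100), c(0.1, 0.1, 0.1))  # 1000 um^3
  df <- data.frame(id = 1:40, z = 5, y = 5, x = 5, response = 1,
                   intensity = 1, edge = FALSE, retained = TRUE)
  sp <- gliamorph:::spot_set(df, 0.8, 0.5, "roi")
  rec <- data.frame(spot = 1:40, cell = 1L, d = c(rep(-0.2, 4),
                                                  rep(3, 36)),
                    class = factor(c(rep("engulfed", 4), rep("free", 36)),
                                   levels = c("free", "contact",
                                              "engulfed")),
                    deep_interior = FALSE, mode = "shell")
  s <- engulfment_summary(rec, sp, roi_full(g), g)
  expect_equal(s$fraction, 0.10)
  expect_equal(s$engulfed, 4L)
  expect_equal(s$engulfed_density, 4)

  empty <- sp[0, ]
  rec0 <- rec[0, ]
  expect_warning(s0 <- engulfment_summary(rec0, empty, roi_full(g), g),
                 "undefined")
  expect_true(is.na(s0$fraction))
})
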