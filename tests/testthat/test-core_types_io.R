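test_that("voxel grids validate sizes and expose physical geometry", {
  g <- voxel_grid(c(50, 64, 64), c(0.1, 0.1, 0.1))
  expect_equal(grid_extent(g), c(5, 6.4, 6.4))
  expect_equal(voxel_volume(g), 1e-3)
  expect_error(voxel_grid(c(10, 10, 10), c(0, 0.1, 0.1)), "positive")
  expect_error(voxel_grid(c(10, 10, 10), c(0.1, -1, 0.1)), "positive")
  # anisotropy is allowed
  expect_silent(voxel_grid(c(10, 10, 10), c(0.5, 0.1, 0.1)))
})

test_that("roi_volume is voxel count times voxel volume", {
  g <- voxel_grid(c(50, 64, 64), c(0.1, 0.1, 0.1))
  expect_equal(roi_volume(roi_bounds(c(0, 0, 0), c(10, 10, 10)), g), 1.0)
  expect_equal(roi_volume(roi_full(g), g), 204.8)
  m <- array(FALSE, dim = g$shape)
  expect_warning(v <- roi_volume(roi_mask(m), g), "no voxels")
  expect_equal(v, 0)
  expect_error(roi_bounds(c(0, 0, 0), c(0, 10, 10)), "empty")
})

test_that("stacks round-trip through OME-TIFF bit-identically", {
  g <- voxel_grid(c(5, 8, 9), c(0.3, 0.11, 0.12))
  set.seed(1)
  st <- multichannel_stack(
    list(iba1 = array(runif(prod(g$shape)) * 300, g$shape),
         agrp = array(runif(prod(g$shape)) * 50, g$shape)),
    g, list(animal = "a1", group = "NCD", region = "PVH", age = "P16"))
  path <- tempfile(fileext = ".ome.tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_identical(st2$channels, st$channels)
  expect_equal(st2$grid$voxel_size, g$voxel_size)
  expect_equal(st2$metadata$group, "NCD")
  expect_equal(names(st2$channels), c("iba1", "agrp"))

  # explicit channel_map, and out-of-range index
  st3 <- read_stack(path, channel_map = c(terminals = 1))
  expect_identical(st3$channels$terminals, st$channels$agrp)
  expect_error(read_stack(path, channel_map = c(iba1 = 5)),
               "channel index out of range")
  unlink(path)
})

test_that("degenerate stacks still write and invalid stacks are rejected", {
  g1 <- voxel_grid(c(1, 6, 7), c(0.2, 0.1, 0.1))  # 1-voxel-thick z
  st <- multichannel_stack(list(iba1 = array(1, g1$shape)), g1)
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_identical(st2$channels$iba1, st$channels$iba1)
  unlink(path)
  expect_error(multichannel_stack(list(), g1), "non-empty")
  expect_error(multichannel_stack(list(a = array(-1, g1$shape)), g1),
               "negative")
  expect_error(
    multichannel_stack(list(a = array(0, c(2, 6, 7))), g1), "shape")
})

test_that("a TIFF without voxel metadata requires an explicit override", {
  # plain TIFF written by the tiff package itself: no OME description
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(20), 4, 5), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  expect_error(read_stack(path), "voxel-size")
  st <- read_stack(path, voxel_size = c(0.1, 0.1, 0.1))
  expect_equal(st$grid$shape, c(1L, 4L, 5L))
  expect_error(read_stack(path, voxel_size = c(0, 0.1, 0.1)),
               "positive")
  unlink(path)
})

test_that("physical measurements scale linearly with voxel size", {
  shape <- c(20L, 20L, 20L)
  set.seed(7)
  m <- array(runif(prod(shape)) < 0.2, shape)
  g1 <- voxel_grid(shape, c(0.1, 0.1, 0.1))
  g2 <- voxel_grid(shape, c(0.2, 0.2, 0.2))
  expect_equal(cell_volume(m, g2), 8 * cell_volume(m, g1))
  r <- roi_bounds(c(0, 0, 0), c(10, 10, 10))
  expect_equal(roi_volume(r, g2), 8 * roi_volume(r, g1))
})

test_that("animal tables round-trip with a comment line", {
  df <- data.frame(animal = c("a1", "a2"), group = c("NCD", "MHFD"),
                   age = "P16", region = "PVH", metric = "len",
                   value = c(1.25, 3.5))
  path <- tempfile(fileext = ".csv")
  write_animal_table(df, path, comment = "config_hash: abc")
  back <- read_animal_table(path)
  expect_equal(back$value, df$value)
  expect_equal(back$animal, df$animal)
  expect_equal(readLines(path, n = 1), "# config_hash: abc")
  unlink(path)
})
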