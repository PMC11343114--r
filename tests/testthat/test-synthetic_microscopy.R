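# The generator: growth law, rendering, ground truth, cohorts, determinism.

test_that("an unbranched single process has exactly its drawn length", {
  mdl <- glia_model(soma_center = c(10, 10, 10), n_primary = 1,
                    branch_rate = 0, mean_segment = 20, segment_cv = 0,
                    max_depth = 1, tortuosity = 0)
  cell <- grow_glia(mdl, seed = 5)
  expect_equal(cell$true_length, 20)
  expect_equal(cell$branch_count, 0L)
  expect_equal(nrow(cell$segments), 1)
})

test_that("growth is deterministic under a fixed seed", {
  mdl <- glia_model(soma_center = c(10, 10, 10))
  a <- grow_glia(mdl, seed = 123)
  b <- grow_glia(mdl, seed = 123)
  expect_identical(a, b)
  c <- grow_glia(mdl, seed = 124)
  expect_false(identical(a$skeleton$nodes, c$skeleton$nodes))
})

test_that("invalid glia parameters are rejected", {
  expect_error(glia_model(process_radius = 0), "radii")
  expect_error(glia_model(n_primary = 0, max_depth = 3), "zero processes")
  expect_error(spot_model(frac_contact = 0.7, frac_engulfed = 0.5),
               "sum to <= 1")
})

test_that("mean branch count matches the analytic branching law", {
  # dispersion 0 so every segment has the same branch probability
  mdl <- glia_model(soma_center = c(20, 20, 20), n_primary = 3,
                    branch_rate = 0.2, mean_segment = 4, segment_cv = 0,
                    max_depth = 3)
  counts <- vapply(1:500, function(s)
    as.numeric(grow_glia(mdl, seed = s)$branch_count), 0)
  expected <- bf_expected_branches(3, 0.2, 4, 3)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-12)
})

test_that("an empty noiseless scene renders all-zero channels", {
  g <- voxel_grid(c(24, 24, 24), c(0.2, 0.2, 0.2))
  sc <- render_scene(list(), spot_model(density = 0), g,
                     noise = noise_model(0, 0), seed = 1)
  expect_true(all(sc$stack$channels$iba1 == 0))
  expect_true(all(sc$stack$channels$agrp == 0))
  expect_equal(nrow(sc$truth$spots), 0)
})

test_that("a spot rendered at a voxel center peaks at that voxel", {
  g <- voxel_grid(c(24, 24, 24), c(0.2, 0.2, 0.2))
  ctr <- matrix((c(12, 12, 12) - 0.5) * 0.2, 1)  # center of voxel (12,12,12)
  sc <- render_scene(list(), spot_model(), g, noise = noise_model(0, 0),
                     seed = 1, spot_centers = ctr)
  expect_equal(arrayInd(which.max(sc$stack$channels$agrp), g$shape)[1, ],
               c(12L, 12L, 12L))
})

test_that("planted class fractions are exact in the ground truth", {
  g <- voxel_grid(c(80, 80, 80), c(0.15, 0.15, 0.15))
  mdl <- glia_model(soma_center = grid_extent(g) / 2, soma_radius = 1.5,
                    n_primary = 3, mean_segment = 2.5, max_depth = 2)
  cell <- grow_glia(mdl, seed = 3, grid = g)
  sm <- spot_model(density = 0.02, frac_engulfed = 0.3, frac_contact = 0.2)
  sc <- render_scene(list(cell), sm, g, seed = 3)
  tab <- table(sc$truth$spots$class)
  n <- nrow(sc$truth$spots)
  expect_equal(unname(tab["engulfed"]), round(0.3 * n))
  expect_equal(unname(tab["contact"]), round(0.2 * n))
})

test_that("noise changes rendered intensities but never the ground truth", {
  g <- voxel_grid(c(48, 48, 48), c(0.2, 0.2, 0.2))
  mdl <- glia_model(soma_center = grid_extent(g) / 2, soma_radius = 1.5,
                    n_primary = 2, mean_segment = 2, max_depth = 1)
  cell <- grow_glia(mdl, seed = 8, grid = g)
  quiet <- render_scene(list(cell), spot_model(density = 0.02), g,
                        noise = noise_model(1, 1), seed = 8)
  loud <- render_scene(list(cell), spot_model(density = 0.02), g,
                       noise = noise_model(25, 1), seed = 8)
  expect_identical(quiet$truth$spots, loud$truth$spots)
  expect_false(identical(quiet$stack$channels$agrp,
                         loud$stack$channels$agrp))
})

test_that("cohorts have the declared layout and are byte-reproducible", {
  g <- voxel_grid(c(32, 32, 32), c(0.3, 0.3, 0.3))
  base <- glia_model(soma_radius = 1.5, n_primary = 2, mean_segment = 2,
                     max_depth = 1)
  spec <- cohort_spec(
    groups = list(NCD = list(glia = base,
                             spots = spot_model(density = 0.005)),
                  MHFD = list(glia = base,
                              spots = spot_model(density = 0.005))),
    animals_per_group = 4, grid = g, master_seed = 11)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  r1 <- generate_cohort(spec, out_dir = d1)
  r2 <- generate_cohort(spec, out_dir = d2)
  expect_equal(nrow(r1$manifest), 8)
  expect_equal(sort(unique(r1$gt_cells$group)), c("MHFD", "NCD"))
  expect_equal(nrow(r1$gt_cells), 8)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
  expect_error(cohort_spec(groups = list(A = list(glia = base)),
                           animals_per_group = 1), ">= 2")
})

test_that("scaled segment lengths plant the intended group length ratio", {
  # group B is a spatial rescaling of group A processes: segment length
  # x 1.87 with branch rate / 1.87 leaves the branching law untouched,
  # so mean total process length scales by exactly 1.87 in expectation
  base <- glia_model(soma_center = c(30, 30, 30), n_primary = 4,
                     branch_rate = 0.4, mean_segment = 4, segment_cv = 0.3,
                     max_depth = 3)
  scaled <- base
  scaled$mean_segment <- base$mean_segment * 1.87
  scaled$branch_rate <- base$branch_rate / 1.87
  la <- vapply(1:400, function(s) grow_glia(base, seed = s)$true_length, 0)
  lb <- vapply(1:400, function(s)
    grow_glia(scaled, seed = 5000 + s)$true_length, 0)
  ratio <- mean(lb) / mean(la)
  se <- ratio * sqrt((sd(la) / mean(la))^2 + (sd(lb) / mean(lb))^2) / 20
  expect_lt(abs(ratio - 1.87), 4 * se)
})
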