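test_that("per-animal aggregation averages within animal, never pools", {
  rec <- data.frame(animal = c("a1", "a1", "a2"), group = "NCD",
                    value = c(10, 20, 30))
  agg <- aggregate_per_animal(rec, "len")
  expect_equal(agg$value, c(15, 30))
  expect_equal(nrow(agg), 2)

  # unbalanced fixture: group mean of animal means != pooled cell mean
  rec2 <- data.frame(animal = c("a1", "a1", "a1", "a2"), group = "NCD",
                     value = c(0, 0, 0, 12))
  agg2 <- aggregate_per_animal(rec2, "len")
  expect_equal(mean(agg2$value), 6)        # mean of animal means
  expect_false(mean(agg2$value) == mean(rec2$value))  # pooled = 3
})

test_that("the unpaired t-test matches the closed-form pooled formula", {
  cmp <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6), variant = "student")
  # closed form: pooled sd 1, se = sqrt(2/3), t = -3 / se
  expect_equal(cmp$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(cmp$t, -3.6742, tolerance = 1e-4)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-10)
  expect_equal(cmp$p, 0.0214, tolerance = 5e-3)
  expect_true(cmp$significant)
  expect_equal(cmp$percent_change, 150)

  same <- unpaired_t_test(c(5, 5, 6), c(5, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t_test(c(0, 0), c(0, 0)), "zero variance")
  expect_error(unpaired_t_test(1, c(1, 2)), "n >= 2")
})

test_that("Welch equals Student for equal sizes and variances", {
  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)  # same spread
  s <- unpaired_t_test(a, b, "student")
  w <- unpaired_t_test(a, b, "welch")
  expect_equal(s$t, w$t)
  expect_equal(s$df, w$df)
  expect_equal(s$p, w$p)
})

test_that("mean_sem and percent_change follow the reporting conventions", {
  s <- mean_sem(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3))
  expect_equal(s$n, 3)
  s1 <- mean_sem(7)
  expect_true(is.na(s1$sem))
  expect_equal(s1$mean, 7)
  set.seed(1); x <- rnorm(10)
  expect_equal(mean_sem(x)$mean, mean_sem(rev(x))$mean)

  expect_equal(percent_change(100, 187), 87)
  expect_equal(percent_change(100, 100), 0)
  expect_error(percent_change(0, 5), "nonzero")
})

test_that("reports have the figure schema and regenerate byte-identically", {
  set.seed(42)
  at <- data.frame(
    animal = rep(sprintf("a%02d", 1:8), times = 2),
    group = rep(rep(c("NCD", "MHFD"), each = 4), 2),
    region = "PVH", age = "P16",
    metric = rep(c("process_length", "complexity"), each = 8),
    value = c(rnorm(4, 100, 10), rnorm(4, 187, 10),
              rnorm(4, 50, 5), rnorm(4, 72, 5)))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  r <- build_report(at, out_dir = d1, reference_group = "NCD",
                    config_hash = "h")
  build_report(at, out_dir = d2, reference_group = "NCD",
               config_hash = "h")
  expect_true(all(c("metric", "n_a", "mean_a", "sem_a", "t", "df", "p",
                    "percent_change", "significant") %in% names(r)))
  expect_equal(nrow(r), 2)
  expect_equal(r$group_a, c("NCD", "NCD"))
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})
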