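# Per-animal aggregation and figure-style group statistics: mean +/- SEM,
# unpaired t-tests, percent change. The animal is the statistical unit
# everywhere; cells and spots are first averaged within animal.

#' Aggregate per-cell/per-spot records to one value per animal
#'
#' One value per animal = the unweighted mean over that animal's records
#' (cells, spots or ROIs). Group means computed downstream are therefore
#' means of animal means, never pooled-cell means.
#'
#' @param records data frame with at least `animal` and a value column.
#' @param metric name stored in the output `metric` column.
#' @param value_col which column to average (default `"value"`).
#' @param by extra grouping columns carried through (default any of
#'   `group`, `region`, `age` present in `records`).
#' @return Data frame with one row per animal (per `by` combination):
#'   `animal, <by...>, metric, value`.
#' @export
aggregate_per_animal <- function(records, metric, value_col = "value",
                                 by = intersect(c("group", "region", "age"),
                                                names(records))) {
  if (!"animal" %in% names(records)) stop("records need an 'animal' column")
  if (!value_col %in% names(records)) stop("missing value column: ", value_col)
  keys <- c("animal", by)
  agg <- stats::aggregate(records[[value_col]], records[keys], mean,
                          na.rm = TRUE)
  names(agg)[ncol(agg)] <- "value"
  agg$metric <- metric
  agg <- agg[do.call(order, agg[keys]), c(keys, "metric", "value")]
  rownames(agg) <- NULL
  agg
}

#' Mean, SEM and n of a sample
#'
#' @param values numeric vector.
#' @return List with `mean`, `sem` (sample sd / sqrt(n); `NA` when n < 2)
#'   and `n`.
#' @export
mean_sem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  list(mean = if (n > 0) mean(values) else NA_real_,
       sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Percent change between two group means
#'
#' `100 * (comparison - reference) / reference`, the reporting convention
#' for group effects (e.g. 100 -> 187 is +87%).
#'
#' @param reference,comparison group means; `reference` must be nonzero.
#' @return Percent change (scalar).
#' @export
percent_change <- function(reference, comparison) {
  if (!is.finite(reference) || reference == 0)
    stop("reference mean must be nonzero")
  100 * (comparison - reference) / reference
}

#' Unpaired two-sample t-test with figure-style summary
#'
#' Two-sided unpaired t-test between two groups of per-animal values,
#' Student (pooled variance, the default) or Welch. Significance is
#' flagged at alpha = 0.05. Group A is the reference for the percent
#' change.
#'
#' @param a,b numeric vectors of per-animal values (each n >= 2).
#' @param variant `"student"` or `"welch"`.
#' @param metric,labels optional metric name and group labels (length 2).
#' @return A `group_comparison` one-row data frame: `metric, group_a,
#'   group_b, n_a, n_b, mean_a, mean_b, sem_a, sem_b, t, df, p,
#'   percent_change, significant`.
#' @export
unpaired_t_test <- function(a, b, variant = c("student", "welch"),
                            metric = "metric", labels = c("A", "B")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  if (sd(a) == 0 && sd(b) == 0) stop("zero variance in both groups")
  tt <- t.test(a, b, var.equal = (variant == "student"))
  sa <- mean_sem(a); sb <- mean_sem(b)
  out <- data.frame(metric = metric, group_a = labels[1], group_b = labels[2],
                    n_a = sa$n, n_b = sb$n, mean_a = sa$mean,
                    mean_b = sb$mean, sem_a = sa$sem, sem_b = sb$sem,
                    t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value,
                    percent_change = percent_change(sa$mean, sb$mean),
                    significant = tt$p.value < 0.05)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Build the per-metric comparison report
#'
#' For every (metric, region, age) cell of a long per-animal table with
#' exactly two groups, runs [unpaired_t_test()] and writes one CSV per
#' comparison plus a combined `report.csv`, in deterministic order and
#' with fixed float formatting, so regeneration from the same table is
#' byte-identical. No multiple-testing correction is applied (stated in
#' the report footer file).
#'
#' @param animal_table long data frame: `animal, group, value, metric` and
#'   optionally `region`, `age` (from [aggregate_per_animal()]).
#' @param out_dir output directory (created if needed); NULL returns the
#'   comparison table without writing.
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param reference_group which group is A in percent change; default the
#'   alphabetically first.
#' @param config_hash optional provenance string written into each CSV.
#' @return The combined comparison data frame (one row per metric-region-
#'   age), invisibly when writing.
#' @export
build_report <- function(animal_table, out_dir = NULL,
                         variant = c("student", "welch"),
                         reference_group = NULL, config_hash = NULL) {
  variant <- match.arg(variant)
  at <- animal_table
  if (!"region" %in% names(at)) at$region <- "all"
  if (!"age" %in% names(at)) at$age <- "all"
  cells <- unique(at[c("metric", "region", "age")])
  cells <- cells[order(cells$metric, cells$region, cells$age), , drop = FALSE]
  rows <- NULL
  for (i in seq_len(nrow(cells))) {
    sub <- at[at$metric == cells$metric[i] & at$region == cells$region[i] &
                at$age == cells$age[i], ]
    grps <- sort(unique(sub$group))
    if (length(grps) != 2) next
    if (!is.null(reference_group) && reference_group %in% grps)
      grps <- c(reference_group, setdiff(grps, reference_group))
    cmp <- tryCatch(
      unpaired_t_test(sub$value[sub$group == grps[1]],
                      sub$value[sub$group == grps[2]],
                      variant = variant,
                      metric = cells$metric[i], labels = grps),
      error = function(e) NULL)  # degenerate metric (all-constant): skip
    if (is.null(cmp)) next
    cmp$region <- cells$region[i]; cmp$age <- cells$age[i]
    rows <- rbind(rows, cmp)
  }
  if (is.null(rows)) stop("no two-group comparisons found")
  rows <- rows[order(rows$metric, rows$region, rows$age), , drop = FALSE]
  rownames(rows) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_len(nrow(rows)))
      write_animal_table(rows[i, , drop = FALSE],
                         file.path(out_dir,
                                   sprintf("%s_%s_%s.csv", rows$metric[i],
                                           rows$region[i], rows$age[i])),
                         comment = config_hash)
    write_animal_table(rows, file.path(out_dir, "report.csv"),
                       comment = config_hash)
    writeLines(c("Values are per-animal means; bars mean +/- SEM.",
                 sprintf("Unpaired %s t-tests, two-sided, alpha = 0.05.",
                         variant),
                 "No multiple-testing correction applied."),
               file.path(out_dir, "README.txt"))
  }
  invisible(rows)
}

#' Bar-with-points plot of one comparison
#'
#' Figure-style panel: group bars of mean +/- SEM with one point per
#' animal. Requires ggplot2.
#'
#' @param animal_table long per-animal table (see [build_report()]).
#' @param metric which metric to plot.
#' @return A ggplot object.
#' @export
plot_comparison <- function(animal_table, metric) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  sub <- animal_table[animal_table$metric == metric, ]
  agg <- do.call(rbind, lapply(split(sub, sub$group), function(g) {
    s <- mean_sem(g$value)
    data.frame(group = g$group[1], mean = s$mean, sem = s$sem)
  }))
  ggplot2::ggplot() +
    ggplot2::geom_col(data = agg,
                      ggplot2::aes(x = group, y = mean),
                      fill = "grey80", color = "black", width = 0.6) +
    ggplot2::geom_errorbar(data = agg,
                           ggplot2::aes(x = group, ymin = mean - sem,
                                        ymax = mean + sem),
                           width = 0.2) +
    ggplot2::geom_jitter(data = sub,
                         ggplot2::aes(x = group, y = value),
                         width = 0.08, size = 2) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_classic()
}
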