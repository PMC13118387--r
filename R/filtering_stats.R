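#' Prevalence filter
#'
#' Retains taxa detected (count >= `presence_threshold`) in at least a
#' fraction `min_prevalence` of the table's samples. With 40 samples the
#' conventional 2.5% cut-off resolves to detection in at least one sample.
#' The filter is idempotent at a fixed threshold; `min_prevalence = 0` is the
#' identity. Retained/removed tallies are attached as the `"filter"`
#' attribute.
#'
#' @param table a `count_table`.
#' @param min_prevalence fraction of samples in `[0, 1]`.
#' @param presence_threshold minimum classified reads that count as detection
#'   (default 1).
#' @return the filtered `count_table` with attribute
#'   `filter = list(min_prevalence, presence_threshold, retained, removed)`.
#' @export
prevalence_filter <- function(table, min_prevalence, presence_threshold = 1) {
  if (n_taxa(table) == 0 || n_samples(table) == 0) {
    stop("cannot prevalence-filter an empty table", call. = FALSE)
  }
  if (min_prevalence < 0 || min_prevalence > 1) {
    stop("min_prevalence must be in [0, 1]", call. = FALSE)
  }
  prev <- rowMeans(table$counts >= presence_threshold)
  keep <- prev >= min_prevalence
  out <- count_table(table$counts[keep, , drop = FALSE], warn_empty = FALSE)
  attr(out, "filter") <- list(min_prevalence = min_prevalence,
                              presence_threshold = presence_threshold,
                              retained = sum(keep), removed = sum(!keep))
  out
}

#' Per-sample classified-read totals
#'
#' @param table a `count_table`.
#' @return named numeric vector of column sums (classified reads).
#' @export
sample_totals <- function(table) {
  colSums(table$counts)
}

#' Saliva-to-biopsy retained-taxa ratio
#'
#' Ratio of the number of taxa retained (after prevalence filtering) in the
#' saliva compartment to the number retained in the biopsy compartment,
#' rounded the way such ratios are conventionally printed (one decimal).
#'
#' @param n_saliva_taxa,n_biopsy_taxa retained-taxa tallies (positive).
#' @param digits decimals to round to (default 1).
#' @return the rounded ratio.
#' @export
taxa_pool_ratio <- function(n_saliva_taxa, n_biopsy_taxa, digits = 1) {
  if (n_biopsy_taxa <= 0) stop("biopsy taxa tally must be positive", call. = FALSE)
  round(n_saliva_taxa / n_biopsy_taxa, digits)
}

#' Group descriptive statistics
#'
#' Per-group n, mean, SD (n-1 denominator), median, and 25th/75th
#' percentiles. Percentiles use linear interpolation (quantile type 7).
#'
#' @param values numeric vector.
#' @param labels group label per value.
#' @return data.frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `median`, `iqr_low`, `iqr_high`.
#' @export
group_descriptives <- function(values, labels) {
  if (length(values) != length(labels)) stop("values and labels differ in length", call. = FALSE)
  if (length(values) == 0) stop("every group needs at least one non-missing value", call. = FALSE)
  labels <- as.character(labels)
  groups <- unique(labels)
  empty <- groups[vapply(groups, function(g) sum(labels == g & !is.na(values)) == 0, logical(1))]
  if (length(empty) > 0 || anyNA(values)) {
    stop("every group needs at least one non-missing value", call. = FALSE)
  }
  out <- lapply(groups, function(g) {
    v <- values[labels == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = q[2], iqr_low = q[1], iqr_high = q[3])
  })
  do.call(rbind, out)
}

welch_stats <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) return(list(t = 0, df = nx + ny - 2, p = NA_real_))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Independent two-sample t-test with bootstrap confidence interval
#'
#' Welch (unequal-variance) t statistic and p-value on the original data,
#' plus a percentile bootstrap confidence interval of the mean difference
#' from `n_boot` stratified (within-group) resamples. Fully reproducible
#' given `seed`; widening `n_boot` cannot change the point estimates.
#'
#' @param x,y numeric vectors (length >= 2 each).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed (mandatory; every resample depends on it).
#' @param conf confidence level of the percentile interval (default 0.95).
#' @param var_equal use the pooled-variance (classical) t instead of Welch.
#' @return object of class `boot_t_test`: list with `t`, `df`, `p`,
#'   `mean_diff` (`mean(x) - mean(y)`), `boot_ci_low`, `boot_ci_high`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_t_test <- function(x, y, n_boot = 1000, seed, conf = 0.95, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least two values per group", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory for the bootstrap", call. = FALSE)
  if (var_equal) {
    ws <- local({
      nx <- length(x); ny <- length(y); df <- nx + ny - 2
      sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
      se2 <- sp2 * (1 / nx + 1 / ny)
      if (se2 == 0) list(t = 0, df = df, p = NA_real_) else {
        t <- (mean(x) - mean(y)) / sqrt(se2)
        list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
      }
    })
  } else {
    ws <- welch_stats(x, y)
  }
  if (is.na(ws$p)) {
    warning("all values identical in both groups: p reported as 1", call. = FALSE)
    ws$p <- 1
  }
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(i) {
    mean(x[sample.int(length(x), replace = TRUE)]) -
      mean(y[sample.int(length(y), replace = TRUE)])
  }, numeric(1))
  ci <- stats::quantile(diffs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        type = 7, names = FALSE)
  structure(list(t = ws$t, df = ws$df, p = ws$p, mean_diff = mean(x) - mean(y),
                 boot_ci_low = ci[1], boot_ci_high = ci[2],
                 n_boot = n_boot, seed = seed),
            class = "boot_t_test")
}

#' @export
print.boot_t_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.1f, p = %.4g\nmean difference = %.4g [%.4g, %.4g] (%d bootstrap resamples, seed %d)\n",
              x$t, x$df, x$p, x$mean_diff, x$boot_ci_low, x$boot_ci_high,
              x$n_boot, x$seed))
  invisible(x)
}

#' Post hoc power of the two-sided two-sample t-test
#'
#' Power under the observed effect, using the pooled SD and the noncentral t
#' distribution: with `ncp = (mean1 - mean2) / (sd_pooled * sqrt(1/n1 + 1/n2))`
#' and `df = n1 + n2 - 2`, power is the probability that `|T|` exceeds the
#' two-sided critical value. This is one of several post hoc conventions;
#' results from other software need not match exactly.
#'
#' @param mean1,sd1,n1 first group's observed mean, SD, and size.
#' @param mean2,sd2,n2 second group's observed mean, SD, and size.
#' @param alpha significance level (default 0.05, two-sided).
#' @return power in `[0, 1]`; equals `alpha` when `mean1 == mean2`.
#' @export
posthoc_power_t <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2", call. = FALSE)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  ncp <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Mann-Whitney U p-value
#'
#' Two-sided rank-sum test (normal approximation with ties), reported
#' alongside the t-test for median-style comparisons.
#'
#' @param x,y numeric vectors.
#' @return p-value.
#' @export
mann_whitney_p <- function(x, y) {
  stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
}
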