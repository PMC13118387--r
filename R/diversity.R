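#' Shannon-Wiener diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive counts, where `p_i` is
#' the relative abundance. Jointly captures richness and evenness: `H = 0`
#' for a single taxon, `H = log(S)` for `S` equally abundant taxa. Natural
#' logarithm by default; pass `base = 2` for bits.
#'
#' @param counts non-negative numeric vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return the index value.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("cannot compute diversity of an all-zero profile", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Per-sample diversity records
#'
#' Richness (detected taxa), Shannon index and classified-read depth for
#' every sample in the table, annotated with compartment and group. Depth is
#' reported alongside deliberately: no rarefaction is applied, so users can
#' see any depth-diversity coupling directly.
#'
#' @param table a `count_table`.
#' @param metadata validated metadata covering the table's samples.
#' @param base Shannon log base.
#' @param presence_threshold reads needed to count a taxon as detected.
#' @return data.frame: `sample_id`, `subject_id`, `compartment`, `group`,
#'   `depth`, `richness`, `shannon`.
#' @export
diversity_records <- function(table, metadata, base = exp(1), presence_threshold = 1) {
  metadata <- validate_metadata(metadata)
  ids <- intersect(sample_names(table), metadata$sample_id)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  m <- table$counts[, ids, drop = FALSE]
  data.frame(sample_id = ids,
             subject_id = meta$subject_id,
             compartment = meta$compartment,
             group = meta$group,
             depth = colSums(m),
             richness = colSums(m >= presence_threshold),
             shannon = apply(m, 2, function(v) {
               if (sum(v) == 0) NA_real_ else shannon_index(v, base = base)
             }),
             row.names = NULL)
}

#' Case-control diversity comparison within a compartment
#'
#' Computes per-sample diversity records for one compartment and compares the
#' Shannon index between cases and controls with [bootstrap_t_test()];
#' observed-effect post hoc power ([posthoc_power_t()]) and a Mann-Whitney
#' p-value are attached.
#'
#' @param table a `count_table`.
#' @param metadata validated metadata.
#' @param compartment `"saliva"` or `"biopsy"`.
#' @param base Shannon log base.
#' @param n_boot,seed bootstrap settings (see [bootstrap_t_test()]).
#' @param alpha significance level for the power computation.
#' @return list with `records` (data.frame), `test` (`boot_t_test`, case vs
#'   control), `power`, `mann_whitney_p`.
#' @export
diversity_by_group <- function(table, metadata, compartment, base = exp(1),
                               n_boot = 1000, seed, alpha = 0.05) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  rec <- diversity_records(table, metadata, base = base)
  rec <- rec[rec$compartment == compartment & !is.na(rec$shannon), , drop = FALSE]
  x <- rec$shannon[rec$group == "case"]
  y <- rec$shannon[rec$group == "control"]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two samples per group in compartment ", compartment, call. = FALSE)
  }
  test <- bootstrap_t_test(x, y, n_boot = n_boot, seed = seed)
  power <- if (stats::sd(x) > 0 && stats::sd(y) > 0) {
    posthoc_power_t(mean(x), stats::sd(x), length(x),
                    mean(y), stats::sd(y), length(y), alpha = alpha)
  } else {
    NA_real_
  }
  list(records = rec, test = test, power = power,
       mann_whitney_p = mann_whitney_p(x, y))
}
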