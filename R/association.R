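#' Spearman rank correlation with midrank tie handling
#'
#' Pearson correlation of average-ranked vectors. For two binary vectors
#' this equals the phi coefficient of the 2x2 contingency table, which is
#' why group-vs-presence correlations take values such as 1/3 for a
#' 4-of-20 vs 0-of-20 presence pattern.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return rho in `[-1, 1]`, or `NA` with a warning when either vector is
#'   constant (rho undefined).
#' @export
spearman_with_ties <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least three observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Two-sided p-value for a Spearman correlation
#'
#' Student-t approximation: `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. `|rho| = 1` is reported as `p = 0` with a
#' warning about the approximation breaking down there.
#'
#' @param rho correlation (vectorized; `NA` propagates).
#' @param n number of paired observations (>= 4).
#' @return two-sided p-value(s).
#' @export
spearman_p <- function(rho, n) {
  if (n < 4) stop("need n >= 4 for the t approximation", call. = FALSE)
  out <- rep(NA_real_, length(rho))
  ext <- !is.na(rho) & abs(rho) >= 1
  if (any(ext)) {
    warning("|rho| = 1: t approximation degenerate, p reported as 0", call. = FALSE)
    out[ext] <- 0
  }
  ok <- !is.na(rho) & !ext
  tstat <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  out[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: sort p ascending, `q_(i) = min_{j >= i}
#' (n * p_(j) / j)`, capped at 1. Never decreases any p; the multiset of
#' outputs is invariant to input order. `NA`s are passed through and do not
#' count toward the number of tests.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p <- pvalues[ok]
  n <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (n > 0) {
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(n / seq(n, 1) * p[o]))[order(o)]
    out[ok] <- q
  }
  out
}

#' Per-taxon Spearman association with case-control membership
#'
#' For each taxon in the table (within one compartment) the group indicator
#' (case = 1, control = 0) is correlated with either the taxon's relative
#' abundance or its binary presence, using midrank Spearman correlation;
#' raw p comes from the t approximation and q from BH-FDR across the
#' compartment's taxa. Both the case view and the mirrored control view
#' (exact negation of rho, identical p/q) are emitted, each sorted by rho
#' descending. Taxa with constant abundance across samples get `NA` rho
#' (one summarizing warning).
#'
#' @param table a `count_table` (typically prevalence-filtered).
#' @param metadata validated metadata.
#' @param compartment `"saliva"` or `"biopsy"`.
#' @param mode `"relative-abundance"` (default) or `"presence"`. Presence
#'   mode reproduces the phi-style correlations seen for shallow profiles.
#' @param presence_threshold reads that count as detection in presence mode.
#' @return data.frame with columns `source` (`"CA"` case view / `"CO"`
#'   control view), `compartment`, `taxon`, `rho`, `p`, `q`, `direction`.
#' @export
group_association_scan <- function(table, metadata, compartment,
                                   mode = c("relative-abundance", "presence"),
                                   presence_threshold = 1) {
  mode <- match.arg(mode)
  compartment <- match.arg(compartment, COMPARTMENTS)
  metadata <- validate_metadata(metadata)
  meta <- metadata[metadata$compartment == compartment &
                     metadata$sample_id %in% sample_names(table), , drop = FALSE]
  if (length(unique(meta$group)) < 2) {
    stop("compartment must contain both groups", call. = FALSE)
  }
  sub <- subset_samples(table, meta$sample_id)
  meta <- meta[match(sample_names(sub), meta$sample_id), , drop = FALSE]
  x <- as.integer(meta$group == "case")
  y_mat <- if (mode == "presence") {
    (sub$counts >= presence_threshold) * 1
  } else {
    relative_abundance(sub)
  }
  rho <- suppressWarnings(
    vapply(seq_len(nrow(y_mat)), function(i) spearman_with_ties(x, y_mat[i, ]), numeric(1))
  )
  if (anyNA(rho)) {
    warning(sum(is.na(rho)), " taxa with constant abundance: rho undefined", call. = FALSE)
  }
  p <- spearman_p(rho, n = length(x))
  q <- bh_fdr(p)
  base <- data.frame(compartment = compartment, taxon = taxa_names(sub),
                     rho = rho, p = p, q = q)
  ca <- base
  ca$source <- "CA"
  ca$direction <- ifelse(is.na(ca$rho), NA_character_,
                         ifelse(ca$rho >= 0, "case-enriched", "control-enriched"))
  co <- base
  co$source <- "CO"
  co$rho <- -co$rho
  co$direction <- ifelse(is.na(co$rho), NA_character_,
                         ifelse(co$rho >= 0, "control-enriched", "case-enriched"))
  ca <- ca[order(-ca$rho, ca$taxon, na.last = TRUE), , drop = FALSE]
  co <- co[order(-co$rho, co$taxon, na.last = TRUE), , drop = FALSE]
  out <- rbind(ca, co)[, c("source", "compartment", "taxon", "rho", "p", "q", "direction")]
  rownames(out) <- NULL
  out
}
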