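#' Taxa-by-sample count table
#'
#' Container for a matrix of classified read counts, with taxa as rows and
#' samples as columns. Counts are absolute classified reads; relative
#' abundances are always derived on demand (see [relative_abundance()]) and
#' never stored, so that no table can be normalized twice. Taxon labels
#' follow the two-token `"Genus species"` convention used by read-level
#' taxonomic classifiers, where `"unknown_species"` is an ordinary species
#' token (`"Gemella unknown_species"` is a valid, distinct taxon).
#'
#' Validation enforces: all cells non-negative integers, unique taxon labels,
#' unique sample IDs. Samples whose column is entirely zero are *flagged*
#' with a warning (and recorded in the `empty_samples` field) but never
#' silently dropped: an empty profile is information, not noise.
#'
#' @param counts numeric matrix of classified read counts (taxa x samples).
#' @param taxa character vector of taxon labels; defaults to `rownames(counts)`.
#' @param samples character vector of sample IDs; defaults to `colnames(counts)`.
#' @param warn_empty warn about all-zero sample columns (default `TRUE`).
#'   Internal callers that subset tables legitimately set this to `FALSE`.
#' @return an object of class `count_table`: a list with elements `counts`
#'   (the labelled integer matrix) and `empty_samples` (character vector of
#'   flagged all-zero sample IDs).
#' @examples
#' ct <- count_table(matrix(c(3, 1, 0, 2), 2, 2,
#'                          dimnames = list(c("Streptococcus oralis",
#'                                            "Gemella unknown_species"),
#'                                          c("s1", "s2"))))
#' n_taxa(ct)
#' @export
count_table <- function(counts, taxa = rownames(counts), samples = colnames(counts),
                        warn_empty = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(taxa) && nrow(counts) == 0) taxa <- character(0)
  if (is.null(samples) && ncol(counts) == 0) samples <- character(0)
  if (is.null(taxa) || is.null(samples)) {
    stop("count_table requires taxon and sample labels", call. = FALSE)
  }
  if (length(taxa) != nrow(counts) || length(samples) != ncol(counts)) {
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  }
  rownames(counts) <- as.character(taxa)
  colnames(counts) <- as.character(samples)
  validate_count_table(structure(list(counts = counts, empty_samples = character(0)),
                                 class = "count_table"),
                       warn_empty = warn_empty)
}

#' Validate a count table
#'
#' @param x a `count_table`.
#' @param warn_empty warn about all-zero sample columns.
#' @return `x`, with `empty_samples` refreshed.
#' @keywords internal
#' @export
validate_count_table <- function(x, warn_empty = TRUE) {
  m <- x$counts
  if (!is.numeric(m)) stop("counts must be numeric", call. = FALSE)
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at taxon '%s', sample '%s': cells must be non-negative integers",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  dup_t <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_t) > 0) {
    stop("duplicate taxon label(s): ", paste(dup_t, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s) > 0) {
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  empty <- colnames(m)[colSums(m) == 0]
  if (warn_empty && length(empty) > 0) {
    warning("all-zero sample column(s) retained: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  x$empty_samples <- empty
  storage.mode(x$counts) <-
    if (length(m) == 0 || max(m) <= .Machine$integer.max) "integer" else "double"
  x
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %s classified reads total\n",
              n_taxa(x), n_samples(x), format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (length(x$empty_samples) > 0) {
    cat("  flagged all-zero samples:", paste(x$empty_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Accessors for count tables
#'
#' @param x a `count_table`.
#' @return `taxa_names()` / `sample_names()` return character vectors;
#'   `n_taxa()` / `n_samples()` return integers.
#' @export
taxa_names <- function(x) rownames(x$counts)

#' @rdname taxa_names
#' @export
sample_names <- function(x) colnames(x$counts)

#' @rdname taxa_names
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname taxa_names
#' @export
n_samples <- function(x) ncol(x$counts)

#' Subset a count table by sample or taxon
#'
#' Row/column order of the retained labels follows the original table.
#' Subsetting can legitimately create all-zero columns (e.g. restricting a
#' paired table to one compartment), so no empty-sample warning is raised;
#' the `empty_samples` field is still refreshed.
#'
#' @param x a `count_table`.
#' @param ids sample IDs to retain (must exist).
#' @param labels taxon labels to retain (must exist).
#' @return a `count_table`.
#' @export
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_names(x))
  if (length(missing) > 0) {
    stop("unknown sample ID(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- sample_names(x)[sample_names(x) %in% ids]
  count_table(x$counts[, keep, drop = FALSE], warn_empty = FALSE)
}

#' @rdname subset_samples
#' @export
subset_taxa <- function(x, labels) {
  missing <- setdiff(labels, taxa_names(x))
  if (length(missing) > 0) {
    stop("unknown taxon label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- taxa_names(x)[taxa_names(x) %in% labels]
  count_table(x$counts[keep, , drop = FALSE], warn_empty = FALSE)
}

#' Per-sample relative abundances
#'
#' Columns are scaled to sum to one. All-zero columns stay zero.
#'
#' @param x a `count_table`.
#' @return numeric matrix with the same dimnames as `x$counts`.
#' @export
relative_abundance <- function(x) {
  m <- x$counts
  tot <- colSums(m)
  sweep(m, 2, pmax(tot, 1), "/")
}
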