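#' Read a taxa-by-sample count table from TSV
#'
#' Expects a tab-separated file whose header row holds sample IDs (first
#' header cell `"taxon"`), first column holds taxon labels, and remaining
#' cells hold classified read counts. Gzipped files are accepted. Parsing is
#' strict: a negative, missing, or non-integer cell aborts with its
#' row/column coordinates; duplicate labels abort naming the offender.
#' Input row and column order is preserved exactly.
#'
#' @param path path to a `.tsv` or `.tsv.gz` file.
#' @return a validated [count_table()].
#' @seealso [write_count_table()] for the inverse; `write %then% read` is the
#'   identity on valid tables.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- read_tsv_strict(path)
  if (ncol(dt) < 2) stop("count table needs a taxon column and at least one sample", call. = FALSE)
  taxa <- dt[[1]]
  samples <- colnames(dt)[-1]
  m <- matrix(NA_real_, nrow = nrow(dt), ncol = length(samples))
  for (j in seq_along(samples)) {
    cell <- dt[[j + 1]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad) > 0) {
      stop(sprintf("cannot parse count '%s' at row %d (taxon '%s'), column '%s': expected a non-negative integer",
                   cell[bad[1]], bad[1], taxa[bad[1]], samples[j]), call. = FALSE)
    }
    m[, j] <- val
  }
  count_table(m, taxa = taxa, samples = samples)
}

#' Write a count table to TSV
#'
#' First header cell is `"taxon"`; cell values are written as integers.
#'
#' @param x a `count_table`.
#' @param path output path (`.gz` suffix gives gzip compression).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(taxon = taxa_names(x), x$counts, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# all-character TSV read; gzipped input is inflated through a connection so
# no optional decompression helper package is needed
read_tsv_strict <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), sep = "\t", header = TRUE,
                      colClasses = "character", data.table = FALSE,
                      check.names = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                      data.table = FALSE, check.names = FALSE)
  }
}

COMPARTMENTS <- c("saliva", "biopsy")
GROUPS <- c("case", "control")

#' Read and validate a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `subject_id`, `compartment`
#' (`saliva`/`biopsy`) and `group` (`case`/`control`); enum tokens are
#' matched case-insensitively. At most one sample per (subject, compartment)
#' is allowed and the group label must be constant within a subject.
#'
#' @param path path to a `.tsv` or `.tsv.gz` file.
#' @return a `data.frame` with the four normalized columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_tsv_strict(path)
  needed <- c("sample_id", "subject_id", "compartment", "group")
  missing <- setdiff(needed, colnames(df))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_metadata(df[, needed])
}

#' Validate (and normalize) sample metadata
#'
#' @param df data.frame with columns `sample_id`, `subject_id`,
#'   `compartment`, `group`.
#' @return the validated data.frame, enum columns lower-cased.
#' @export
validate_metadata <- function(df) {
  df$compartment <- tolower(trimws(df$compartment))
  df$group <- tolower(trimws(df$group))
  bad_c <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad_c) > 0) {
    stop(sprintf("unknown compartment token(s) %s; allowed: %s",
                 paste(sQuote(bad_c), collapse = ", "),
                 paste(COMPARTMENTS, collapse = ", ")), call. = FALSE)
  }
  bad_g <- setdiff(unique(df$group), GROUPS)
  if (length(bad_g) > 0) {
    stop(sprintf("unknown group token(s) %s; allowed: %s",
                 paste(sQuote(bad_g), collapse = ", "),
                 paste(GROUPS, collapse = ", ")), call. = FALSE)
  }
  dup_s <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup_s) > 0) {
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$subject_id, df$compartment, sep = "\r")
  dup <- df[duplicated(key), , drop = FALSE]
  if (nrow(dup) > 0) {
    stop(sprintf("more than one %s sample for subject '%s'",
                 dup$compartment[1], dup$subject_id[1]), call. = FALSE)
  }
  g_per_subject <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  if (any(g_per_subject > 1)) {
    stop("group label not constant within subject(s): ",
         paste(names(g_per_subject)[g_per_subject > 1], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_metadata
#' @param df metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Build subject-level saliva/biopsy pairs
#'
#' One pair per subject possessing *both* compartments. Subjects missing a
#' compartment are excluded from the sharing analysis only (per-compartment
#' statistics still see their single sample); the excluded subject IDs are
#' reported via a message and attached as the `"excluded"` attribute.
#'
#' @param metadata validated metadata (see [read_metadata()]).
#' @param table optional `count_table`; when given, every paired sample ID
#'   must exist in it.
#' @return data.frame with columns `subject_id`, `group`, `saliva_sample`,
#'   `biopsy_sample`; attribute `excluded` lists incomplete subjects.
#' @export
build_pairs <- function(metadata, table = NULL) {
  metadata <- validate_metadata(metadata)
  subjects <- unique(metadata$subject_id)
  rows <- lapply(subjects, function(s) {
    sub <- metadata[metadata$subject_id == s, , drop = FALSE]
    sal <- sub$sample_id[sub$compartment == "saliva"]
    bio <- sub$sample_id[sub$compartment == "biopsy"]
    if (length(sal) == 1 && length(bio) == 1) {
      data.frame(subject_id = s, group = sub$group[1],
                 saliva_sample = sal, biopsy_sample = bio)
    } else {
      NULL
    }
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    pairs <- data.frame(subject_id = character(0), group = character(0),
                        saliva_sample = character(0), biopsy_sample = character(0))
  }
  excluded <- setdiff(subjects, pairs$subject_id)
  if (length(excluded) > 0) {
    message("excluded from sharing analysis (missing one compartment): ",
            paste(excluded, collapse = ", "))
  }
  if (!is.null(table)) {
    ids <- c(pairs$saliva_sample, pairs$biopsy_sample)
    missing <- setdiff(ids, sample_names(table))
    if (length(missing) > 0) {
      stop("paired sample ID(s) absent from count table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  attr(pairs, "excluded") <- excluded
  pairs
}
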