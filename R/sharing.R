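#' Presence set of a sample
#'
#' Taxa detected in a profile at a read-count threshold. The default of one
#' classified read is the only detection rule consistent with a 2.5%-of-40
#' prevalence filter (which itself resolves to "seen in at least one
#' sample"); raising the threshold can only shrink the set.
#'
#' @param sample_counts named numeric vector (taxa as names).
#' @param threshold minimum classified reads (>= 1, default 1).
#' @return character vector of detected taxon labels, in input order.
#' @export
presence_set <- function(sample_counts, threshold = 1) {
  if (threshold < 1) stop("presence threshold must be at least 1 read", call. = FALSE)
  names(sample_counts)[sample_counts >= threshold]
}

#' Shared taxa of one subject
#'
#' Intersection of the presence sets of a subject's saliva and biopsy
#' samples: the taxa detected in both compartments of the same person.
#'
#' @param pair one subject pair: a list or one-row data.frame with
#'   `subject_id`, `group`, `saliva_sample`, `biopsy_sample`.
#' @param table a `count_table` containing both samples.
#' @param threshold presence threshold in reads.
#' @return object of class `subject_sharing`: list with `subject_id`,
#'   `group`, `shared` (taxon labels, table row order), `k` (its size).
#' @export
shared_taxa <- function(pair, table, threshold = 1) {
  ids <- c(pair$saliva_sample, pair$biopsy_sample)
  missing <- setdiff(ids, sample_names(table))
  if (length(missing) > 0) {
    stop("sample(s) not in table: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sal <- presence_set(table$counts[, pair$saliva_sample], threshold)
  bio <- presence_set(table$counts[, pair$biopsy_sample], threshold)
  shared <- taxa_names(table)[taxa_names(table) %in% intersect(sal, bio)]
  structure(list(subject_id = pair$subject_id, group = pair$group,
                 shared = shared, k = length(shared)),
            class = "subject_sharing")
}

#' Per-subject sharing records for a cohort
#'
#' @param pairs data.frame of subject pairs (see [build_pairs()]).
#' @param table a `count_table`.
#' @param threshold presence threshold in reads.
#' @return list of `subject_sharing` records, class `sharing_records`.
#' @export
sharing_records <- function(pairs, table, threshold = 1) {
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    shared_taxa(pairs[i, , drop = FALSE], table, threshold)
  })
  structure(recs, class = "sharing_records")
}

#' Flatten sharing records to a data.frame
#'
#' @param records a `sharing_records` list.
#' @return data.frame: `subject_id`, `group`, `k`, `shared_taxa`
#'   (semicolon-joined labels).
#' @export
sharing_records_df <- function(records) {
  data.frame(subject_id = vapply(records, `[[`, character(1), "subject_id"),
             group = vapply(records, `[[`, character(1), "group"),
             k = vapply(records, `[[`, integer(1), "k"),
             shared_taxa = vapply(records, function(r) paste(r$shared, collapse = "; "),
                                  character(1)))
}

#' Group-level sharing summary
#'
#' For every taxon appearing in at least one shared set: the number (and
#' percentage) of case and control subjects sharing it between mouth and
#' stomach, the absolute percentage difference (case minus control), the
#' relative difference `(pct_case - pct_control) / pct_case` (undefined,
#' `NA`, when the case share is zero), and an exclusivity flag
#' (`"only-case"` / `"only-control"` / `""`). Rows are sorted by `pct_diff`
#' descending, ties by case shared count descending, then taxon label.
#'
#' @param records a `sharing_records` list covering both groups.
#' @param group_sizes named vector `c(case = ..., control = ...)`; defaults
#'   to the record counts per group.
#' @param top_n optionally truncate to the top N rows (report views of the
#'   kind "top twelve shared taxa").
#' @return data.frame with columns `taxon`, `shared_count_case`,
#'   `shared_pct_case`, `shared_count_control`, `shared_pct_control`,
#'   `pct_diff`, `rel_diff`, `exclusivity`.
#' @export
sharing_summary <- function(records, group_sizes = NULL, top_n = NULL) {
  grp <- vapply(records, `[[`, character(1), "group")
  if (is.null(group_sizes)) {
    group_sizes <- c(case = sum(grp == "case"), control = sum(grp == "control"))
  }
  if (any(group_sizes[GROUPS] <= 0) || anyNA(group_sizes[GROUPS])) {
    stop("both group sizes must be positive", call. = FALSE)
  }
  count_in <- function(g) {
    taxa <- unlist(lapply(records[grp == g], `[[`, "shared"), use.names = FALSE)
    table(taxa)
  }
  tab_ca <- count_in("case")
  tab_co <- count_in("control")
  universe <- sort(union(names(tab_ca), names(tab_co)))
  if (length(universe) == 0) {
    return(data.frame(taxon = character(0),
                      shared_count_case = integer(0), shared_pct_case = numeric(0),
                      shared_count_control = integer(0), shared_pct_control = numeric(0),
                      pct_diff = numeric(0), rel_diff = numeric(0),
                      exclusivity = character(0)))
  }
  cnt_ca <- ifelse(universe %in% names(tab_ca), as.integer(tab_ca[universe]), 0L)
  cnt_co <- ifelse(universe %in% names(tab_co), as.integer(tab_co[universe]), 0L)
  pct_ca <- 100 * cnt_ca / group_sizes[["case"]]
  pct_co <- 100 * cnt_co / group_sizes[["control"]]
  out <- data.frame(taxon = universe,
                    shared_count_case = cnt_ca,
                    shared_pct_case = pct_ca,
                    shared_count_control = cnt_co,
                    shared_pct_control = pct_co,
                    pct_diff = pct_ca - pct_co,
                    rel_diff = ifelse(pct_ca > 0, 100 * (pct_ca - pct_co) / pct_ca, NA_real_),
                    exclusivity = ifelse(cnt_ca > 0 & cnt_co == 0, "only-case",
                                         ifelse(cnt_co > 0 & cnt_ca == 0, "only-control", "")))
  out <- out[order(-out$pct_diff, -out$shared_count_case, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Distribution of shared-taxa counts within a group
#'
#' Histogram of `k` (number of shared taxa per subject) over the subjects of
#' one group, with percentages of the group size. Counts always sum to the
#' group size.
#'
#' @param records a `sharing_records` list covering all subjects of `group`.
#' @param group `"case"` or `"control"`.
#' @return data.frame: `k` (0 up to the maximum observed), `count`, `pct`.
#' @export
sharing_distribution <- function(records, group) {
  group <- match.arg(group, GROUPS)
  ks <- vapply(records, `[[`, integer(1), "k")[
    vapply(records, `[[`, character(1), "group") == group]
  n <- length(ks)
  kmax <- if (n == 0) 0L else max(ks)
  count <- vapply(0:kmax, function(k) sum(ks == k), integer(1))
  data.frame(k = 0:kmax, count = count,
             pct = if (n == 0) rep(NA_real_, kmax + 1) else 100 * count / n)
}

#' Group-exclusive shared taxa
#'
#' Taxa shared between mouth and stomach in at least one subject of one
#' group and in no subject of the other.
#'
#' @param summary output of [sharing_summary()].
#' @return list with character vectors `case_only` and `control_only`.
#' @export
exclusive_taxa <- function(summary) {
  list(case_only = summary$taxon[summary$exclusivity == "only-case"],
       control_only = summary$taxon[summary$exclusivity == "only-control"])
}

#' Co-sharing patterns
#'
#' For every taxon appearing in any shared set: whether it is *never shared
#' alone* (every record containing it has `k >= 2`) and the multiset of
#' partner taxa it co-occurs with across records.
#'
#' @param records a `sharing_records` list.
#' @return data.frame: `taxon`, `n_records`, `never_alone`, `partners`
#'   (list-column of character multisets; may repeat a partner seen in
#'   several records).
#' @export
co_sharing_patterns <- function(records) {
  sets <- lapply(records, `[[`, "shared")
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    return(data.frame(taxon = character(0), n_records = integer(0),
                      never_alone = logical(0),
                      partners = I(list())))
  }
  rows <- lapply(universe, function(tx) {
    containing <- sets[vapply(sets, function(s) tx %in% s, logical(1))]
    partners <- unlist(lapply(containing, function(s) setdiff(s, tx)), use.names = FALSE)
    data.frame(taxon = tx, n_records = length(containing),
               never_alone = all(vapply(containing, length, integer(1)) >= 2),
               partners = I(list(sort(partners))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
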