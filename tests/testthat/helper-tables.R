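# Fixtures built in code: the published sharing tables re-encoded as
# per-subject shared-taxa sets, plus small count-table builders.

SO <- "Streptococcus oralis"
SM <- "Streptococcus mitis"
PH <- "Prevotella histicola"
GS <- "Gemella sanguinis"

make_record <- function(subject_id, group, shared) {
  structure(list(subject_id = subject_id, group = group,
                 shared = shared, k = length(shared)),
            class = "subject_sharing")
}

records_from_sets <- function(case_sets, control_sets) {
  recs <- c(
    lapply(seq_along(case_sets), function(i)
      make_record(sprintf("CA%02d", i), "case", case_sets[[i]])),
    lapply(seq_along(control_sets), function(i)
      make_record(sprintf("CO%02d", i), "control", control_sets[[i]])))
  structure(recs, class = "sharing_records")
}

# the thirteen case sharing combinations (7 subjects share nothing):
# 2x{SO}, 1x{PH}, 2x{SM}, 2x{SO,SM}, 2x{SM,PH}, 2x{GS,SO,SM}, 2x{GS,PH,SO,SM}
table4_case_sets <- function() {
  c(replicate(7, character(0), simplify = FALSE),
    replicate(2, SO, simplify = FALSE),
    list(PH),
    replicate(2, SM, simplify = FALSE),
    replicate(2, c(SO, SM), simplify = FALSE),
    replicate(2, c(SM, PH), simplify = FALSE),
    replicate(2, c(GS, SO, SM), simplify = FALSE),
    replicate(2, c(GS, PH, SO, SM), simplify = FALSE))
}

# control-group sharing consistent with the published summary restricted to
# the same four taxa: SO shared by 2 subjects, SM by 6, PH by 1, GS by 0
table4_control_sets <- function() {
  c(list(c(SO, SM), c(SO, SM), SM, SM, SM, c(SM, PH)),
    replicate(14, character(0), simplify = FALSE))
}

table4_records <- function() {
  records_from_sets(table4_case_sets(), table4_control_sets())
}

# the full published top-twelve summary: per-taxon case/control shared counts
table3_counts <- function() {
  data.frame(
    taxon = c(SO, SM, PH,
              "Fusobacterium pseudoperiodonticum", GS,
              "Gemella unknown_species", "Veillonella rogosae",
              "Streptococcus infantis", "Streptococcus pseudopneumoniae",
              "Porphyromonas unknown_species", "Cutibacterium unknown_species",
              "Prevotella nanceiensis"),
    case = c(8L, 10L, 5L, 4L, 4L, 4L, 4L, 4L, 4L, 5L, 4L, 4L),
    control = c(2L, 6L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L))
}

# any subject assignment with the right per-taxon tallies works for
# count/exclusivity checks: give taxon t to the first count[t] subjects
table3_records <- function(n_case = 20, n_control = 20) {
  cnt <- table3_counts()
  case_sets <- lapply(seq_len(n_case), function(i) cnt$taxon[cnt$case >= i])
  control_sets <- lapply(seq_len(n_control), function(i) cnt$taxon[cnt$control >= i])
  records_from_sets(case_sets, control_sets)
}

# encode per-subject sharing sets as a paired count table + metadata, with
# non-shared filler taxa in each compartment
sets_as_cohort <- function(case_sets, control_sets) {
  sets <- c(case_sets, control_sets)
  groups <- rep(c("case", "control"), c(length(case_sets), length(control_sets)))
  subjects <- sprintf("S%02d", seq_along(sets))
  taxa <- c(SO, SM, PH, GS, "Oralfiller unknown_species", "Gastrofiller unknown_species")
  sal_ids <- paste0(subjects, "_SAL")
  bio_ids <- paste0(subjects, "_BIO")
  m <- matrix(0L, length(taxa), 2 * length(sets),
              dimnames = list(taxa, c(rbind(sal_ids, bio_ids))))
  for (i in seq_along(sets)) {
    m[c(sets[[i]], "Oralfiller unknown_species"), sal_ids[i]] <- 5L
    m[c(sets[[i]], "Gastrofiller unknown_species"), bio_ids[i]] <- 3L
  }
  list(table = count_table(m, warn_empty = FALSE),
       metadata = data.frame(sample_id = c(rbind(sal_ids, bio_ids)),
                             subject_id = rep(subjects, each = 2),
                             compartment = rep(c("saliva", "biopsy"), length(sets)),
                             group = rep(groups, each = 2)))
}

toy_table <- function(counts, taxa = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(taxa)) taxa <- sprintf("Genus%02d unknown_species", seq_len(nrow(counts)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(counts)))
  count_table(counts, taxa = taxa, samples = samples, warn_empty = FALSE)
}

small_params <- function(n_case = 8, n_control = 8, oral_pool = 60,
                         gastric_pool = 30, pool_overlap = 8,
                         translocators = 3, ...) {
  # small cohort for fast pipeline-level tests
  cohort_params(n_case = n_case, n_control = n_control, oral_pool = oral_pool,
                gastric_pool = gastric_pool, pool_overlap = pool_overlap,
                translocators = translocators, ...)
}

phi_coefficient <- function(a, b, c, d) {
  # 2x2 table: rows = group (case/control), cols = presence (yes/no)
  (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
}
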