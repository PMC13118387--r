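#' Parameters for a synthetic paired oral-gastric cohort
#'
#' Defaults emulate a 20-case / 20-control shallow-shotgun cohort in which
#' every subject contributes one deep saliva profile (log-normal depth,
#' median ~26,000 classified reads) and one shallow gastric biopsy profile
#' (log-normal depth; case median ~159 reads with implied mean ~325, control
#' median ~113 with implied mean ~162). The oral pool holds 500 taxa, the
#' gastric pool 130, of which `pool_overlap` are oral taxa also resident in
#' the stomach (so some oral-gastric sharing occurs in controls too). Taxon
#' base abundances are log-normal (`taxon_abundance_shape`), jittered per
#' sample (`taxon_noise_sd`), and reads are drawn multinomially at the drawn
#' depth. Case biopsies are (a) concentrated by raising relative abundances
#' to the power `1 / case_biopsy_evenness_penalty` (penalty < 1 lowers
#' evenness, hence Shannon diversity, in cases) and (b) augmented with
#' `translocators` designated abundant oral taxa, each seeded independently
#' with probability `transloc_prob` per case subject at relative abundance
#' `transloc_rel_abundance`. Translocators are drawn from the most abundant
#' oral taxa outside the gastric pool (translocated species are core oral
#' commensals), so a seeded taxon is reliably detectable in the donor's
#' saliva.
#'
#' @param n_case,n_control subjects per group.
#' @param oral_pool,gastric_pool pool sizes (taxa).
#' @param pool_overlap gastric-pool members drawn from the oral pool.
#' @param oral_depth_log_mean,oral_depth_log_sd log-normal saliva depth.
#' @param biopsy_depth_case_log_mean,biopsy_depth_case_log_sd log-normal
#'   case biopsy depth.
#' @param biopsy_depth_control_log_mean,biopsy_depth_control_log_sd
#'   log-normal control biopsy depth.
#' @param taxon_abundance_shape log-normal SD of taxon base abundances.
#' @param taxon_noise_sd log-normal SD of per-sample abundance jitter.
#' @param case_biopsy_evenness_penalty factor in (0, 1]; 1 disables the
#'   case-biopsy evenness suppression.
#' @param translocators number k of designated oral translocator taxa.
#' @param transloc_prob per-case, per-translocator seeding probability.
#' @param transloc_rel_abundance seeded relative abundance in the biopsy.
#' @param seed integer seed; same seed and parameters give a bit-identical
#'   cohort.
#' @return object of class `cohort_params` (a validated list).
#' @export
cohort_params <- function(n_case = 20, n_control = 20,
                          oral_pool = 500, gastric_pool = 130, pool_overlap = 30,
                          oral_depth_log_mean = log(26000), oral_depth_log_sd = 0.55,
                          biopsy_depth_case_log_mean = log(159),
                          biopsy_depth_case_log_sd = 1.2,
                          biopsy_depth_control_log_mean = log(113),
                          biopsy_depth_control_log_sd = 0.85,
                          taxon_abundance_shape = 2.0, taxon_noise_sd = 0.6,
                          case_biopsy_evenness_penalty = 0.85,
                          translocators = 4, transloc_prob = 0.2,
                          transloc_rel_abundance = 0.05,
                          seed = 1L) {
  p <- list(n_case = n_case, n_control = n_control,
            oral_pool = oral_pool, gastric_pool = gastric_pool,
            pool_overlap = pool_overlap,
            oral_depth_log_mean = oral_depth_log_mean,
            oral_depth_log_sd = oral_depth_log_sd,
            biopsy_depth_case_log_mean = biopsy_depth_case_log_mean,
            biopsy_depth_case_log_sd = biopsy_depth_case_log_sd,
            biopsy_depth_control_log_mean = biopsy_depth_control_log_mean,
            biopsy_depth_control_log_sd = biopsy_depth_control_log_sd,
            taxon_abundance_shape = taxon_abundance_shape,
            taxon_noise_sd = taxon_noise_sd,
            case_biopsy_evenness_penalty = case_biopsy_evenness_penalty,
            translocators = translocators, transloc_prob = transloc_prob,
            transloc_rel_abundance = transloc_rel_abundance,
            seed = as.integer(seed))
  if (p$n_case < 1 || p$n_control < 1) stop("need at least one subject per group", call. = FALSE)
  if (p$pool_overlap < 0 || p$pool_overlap >= p$gastric_pool) {
    stop("pool_overlap must be in [0, gastric_pool)", call. = FALSE)
  }
  if (p$pool_overlap > p$oral_pool) stop("pool_overlap exceeds oral pool", call. = FALSE)
  if (p$translocators > p$oral_pool - p$pool_overlap) {
    stop("not enough oral-exclusive taxa for the requested translocators", call. = FALSE)
  }
  if (p$transloc_prob < 0 || p$transloc_prob > 1) stop("transloc_prob must be in [0, 1]", call. = FALSE)
  if (p$transloc_rel_abundance < 0 || p$translocators * p$transloc_rel_abundance >= 1) {
    stop("total seeded relative abundance must stay below 1", call. = FALSE)
  }
  if (p$case_biopsy_evenness_penalty <= 0 || p$case_biopsy_evenness_penalty > 1) {
    stop("case_biopsy_evenness_penalty must lie in (0, 1]", call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

#' Generate a synthetic paired saliva/biopsy cohort
#'
#' See [cohort_params()] for the generative model. Per-sample totals equal
#' the drawn depths exactly (multinomial conservation, preserved also under
#' translocator seeding, whose reads are reserved out of the drawn depth
#' with a floor of one read per seeded taxon).
#'
#' @param params a `cohort_params` object.
#' @return list with elements `table` (a [count_table()] over the union of
#'   both pools and all 2 x (n_case + n_control) samples), `metadata`
#'   (data.frame as consumed by [build_pairs()]), and `truth` (ground-truth
#'   bookkeeping: `translocators`, logical `seeded` matrix of case subjects
#'   x translocators, `depths` named vector of drawn depths, `params`,
#'   `seed`).
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  p <- params
  set.seed(p$seed)

  oral_taxa <- sprintf("Oralibacterium sp%04d", seq_len(p$oral_pool))
  overlap_taxa <- if (p$pool_overlap > 0) sample(oral_taxa, p$pool_overlap) else character(0)
  gastric_taxa <- c(overlap_taxa,
                    sprintf("Gastribacterium sp%04d", seq_len(p$gastric_pool - p$pool_overlap)))
  all_taxa <- c(oral_taxa, setdiff(gastric_taxa, oral_taxa))

  oral_base <- stats::rlnorm(p$oral_pool, 0, p$taxon_abundance_shape)
  names(oral_base) <- oral_taxa
  gastric_base <- stats::rlnorm(length(gastric_taxa), 0, p$taxon_abundance_shape)
  names(gastric_base) <- gastric_taxa

  candidates <- setdiff(oral_taxa, gastric_taxa)
  translocators <- if (p$translocators > 0) {
    candidates[order(-oral_base[candidates])][seq_len(p$translocators)]
  } else {
    character(0)
  }

  n_sub <- p$n_case + p$n_control
  subjects <- sprintf("S%03d", seq_len(n_sub))
  groups <- rep(c("case", "control"), c(p$n_case, p$n_control))
  sal_ids <- paste0(subjects, "_SAL")
  bio_ids <- paste0(subjects, "_BIO")

  counts <- matrix(0L, nrow = length(all_taxa), ncol = 2 * n_sub,
                   dimnames = list(all_taxa, c(rbind(sal_ids, bio_ids))))
  seeded <- matrix(FALSE, nrow = p$n_case, ncol = p$translocators,
                   dimnames = list(subjects[seq_len(p$n_case)], translocators))
  depths <- stats::setNames(numeric(2 * n_sub), colnames(counts))

  draw_depth <- function(meanlog, sdlog) max(1, round(stats::rlnorm(1, meanlog, sdlog)))

  for (i in seq_len(n_sub)) {
    is_case <- groups[i] == "case"
    # saliva
    w <- oral_base * stats::rlnorm(p$oral_pool, 0, p$taxon_noise_sd)
    depth <- draw_depth(p$oral_depth_log_mean, p$oral_depth_log_sd)
    counts[oral_taxa, sal_ids[i]] <- stats::rmultinom(1, depth, w / sum(w))[, 1]
    depths[sal_ids[i]] <- depth
    # biopsy
    w <- gastric_base * stats::rlnorm(length(gastric_base), 0, p$taxon_noise_sd)
    if (is_case && p$case_biopsy_evenness_penalty < 1) {
      w <- w^(1 / p$case_biopsy_evenness_penalty)
    }
    prob <- w / sum(w)
    depth <- if (is_case) {
      draw_depth(p$biopsy_depth_case_log_mean, p$biopsy_depth_case_log_sd)
    } else {
      draw_depth(p$biopsy_depth_control_log_mean, p$biopsy_depth_control_log_sd)
    }
    bio_counts <- stats::setNames(integer(length(all_taxa)), all_taxa)
    if (is_case && p$translocators > 0) {
      on_flags <- stats::runif(p$translocators) < p$transloc_prob
      seeded[i, ] <- on_flags
      # reserve seeded reads (>= 1 each) out of the drawn depth, then draw the
      # remainder multinomially from the gastric community
      reserve <- integer(0)
      if (any(on_flags)) {
        per <- pmax(1L, round(depth * p$transloc_rel_abundance))
        reserve <- rep(per, sum(on_flags))
        overshoot <- sum(reserve) - depth
        while (overshoot > 0) { # shallow draw: trim reservations to fit depth
          j <- which.max(reserve)
          cut <- min(overshoot, reserve[j] - (if (sum(reserve > 0) > 1) 0L else 1L))
          if (cut == 0) break
          reserve[j] <- reserve[j] - cut
          overshoot <- overshoot - cut
        }
        bio_counts[translocators[on_flags]] <- reserve
      }
      rest <- depth - sum(reserve)
      if (rest > 0) {
        drawn <- stats::rmultinom(1, rest, prob)[, 1]
        bio_counts[gastric_taxa] <- bio_counts[gastric_taxa] + drawn
      }
    } else {
      bio_counts[gastric_taxa] <- stats::rmultinom(1, depth, prob)[, 1]
    }
    counts[, bio_ids[i]] <- bio_counts
    depths[bio_ids[i]] <- depth
  }

  metadata <- data.frame(
    sample_id = c(rbind(sal_ids, bio_ids)),
    subject_id = rep(subjects, each = 2),
    compartment = rep(c("saliva", "biopsy"), n_sub),
    group = rep(groups, each = 2))

  table <- count_table(counts, warn_empty = FALSE)
  truth <- structure(list(translocators = translocators, seeded = seeded,
                          depths = depths, params = p, seed = p$seed),
                     class = "cohort_truth")
  list(table = table, metadata = metadata, truth = truth)
}

#' Evaluate translocator recovery on a synthetic cohort
#'
#' Compares analysis output against generator ground truth. Three recovery
#' views are reported: `sensitivity_taxon`, the fraction of translocator
#' taxa recovered as case-exclusive shared taxa; `sensitivity_seeded`, the
#' fraction of seeded (case subject, translocator) events present in that
#' subject's shared set (resolves saturation of the taxon-level view at high
#' seeding probability); and, when an association scan is supplied,
#' `sensitivity_association`, the fraction of translocators among the
#' top-k case-view biopsy rows by rho (k = number of translocators). The
#' false-positive rate is the fraction of non-translocator taxa in the
#' cohort flagged case-exclusive.
#'
#' @param case_only character vector of case-exclusive shared taxa
#'   (see [exclusive_taxa()]).
#' @param records the `sharing_records` the exclusivity call came from.
#' @param truth the generator's `cohort_truth`.
#' @param association optional output of [group_association_scan()] on the
#'   biopsy compartment.
#' @return list with the three sensitivities (taxon/seeded are `NA` when no
#'   translocators or no seeding events exist) and `fpr`.
#' @export
evaluate_recovery <- function(case_only, records, truth, association = NULL) {
  universe <- c(sprintf("Oralibacterium sp%04d", seq_len(truth$params$oral_pool)),
                sprintf("Gastribacterium sp%04d",
                        seq_len(truth$params$gastric_pool - truth$params$pool_overlap)))
  stray <- setdiff(case_only, universe)
  if (length(stray) > 0) {
    stop("output taxa not in the generated cohort: ", paste(stray, collapse = ", "),
         call. = FALSE)
  }
  k <- length(truth$translocators)
  sens_taxon <- if (k == 0) NA_real_ else mean(truth$translocators %in% case_only)
  n_events <- sum(truth$seeded)
  sens_seeded <- if (n_events == 0) NA_real_ else {
    shared_by <- stats::setNames(lapply(records, `[[`, "shared"),
                                 vapply(records, `[[`, character(1), "subject_id"))
    hits <- 0L
    for (s in rownames(truth$seeded)) {
      on <- colnames(truth$seeded)[truth$seeded[s, ]]
      hits <- hits + sum(on %in% shared_by[[s]])
    }
    hits / n_events
  }
  sens_assoc <- if (is.null(association) || k == 0) NA_real_ else {
    ca <- association[association$source == "CA" & !is.na(association$rho), , drop = FALSE]
    top <- utils::head(ca$taxon[order(-ca$rho)], k)
    mean(truth$translocators %in% top)
  }
  n_non <- length(universe) - k
  fpr <- if (n_non == 0) NA_real_ else length(setdiff(case_only, truth$translocators)) / n_non
  list(sensitivity_taxon = sens_taxon, sensitivity_seeded = sens_seeded,
       sensitivity_association = sens_assoc, fpr = fpr)
}
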