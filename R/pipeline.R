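#' Run configuration
#'
#' Every tunable of the pipeline, with a recorded default. Either both input
#' paths or a `synthetic` parameter set must be supplied. The configuration
#' is echoed verbatim into the output directory, so a run is always a pure
#' function of (inputs, config, seed).
#'
#' @param input_counts,input_metadata TSV paths (ignored when `synthetic`
#'   is given).
#' @param synthetic optional [cohort_params()] (or plain list of its
#'   arguments) for a generated cohort.
#' @param presence_threshold reads counting as detection (default 1).
#' @param prevalence prevalence cut-off fraction (default 0.025).
#' @param shannon_base Shannon log base (default natural log).
#' @param n_boot bootstrap resamples (default 1000).
#' @param n_perm label permutations for the beta-diversity test (default 999).
#' @param alpha significance level (default 0.05).
#' @param association_mode `"relative-abundance"` or `"presence"`.
#' @param top_n rows kept in the shared-taxa report table (default 12).
#' @param seed integer master seed.
#' @param out_dir output directory (created if absent).
#' @return object of class `run_config`.
#' @export
run_config <- function(input_counts = NULL, input_metadata = NULL, synthetic = NULL,
                       presence_threshold = 1, prevalence = 0.025,
                       shannon_base = exp(1), n_boot = 1000, n_perm = 999,
                       alpha = 0.05, association_mode = "relative-abundance",
                       top_n = 12, seed = 1L, out_dir) {
  if (is.null(synthetic) && (is.null(input_counts) || is.null(input_metadata))) {
    stop("supply either input_counts + input_metadata or synthetic parameters", call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_params")) {
    synthetic <- do.call(cohort_params, as.list(synthetic))
  }
  structure(list(input_counts = input_counts, input_metadata = input_metadata,
                 synthetic = synthetic, presence_threshold = presence_threshold,
                 prevalence = prevalence, shannon_base = shannon_base,
                 n_boot = n_boot, n_perm = n_perm, alpha = alpha,
                 association_mode = match.arg(association_mode,
                                              c("relative-abundance", "presence")),
                 top_n = top_n, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

fmt_rho <- function(x) sprintf("%.4f", x)
fmt_p <- function(x) sprintf("%.3f", x)
fmt_pct <- function(x) sprintf("%d%%", round(x))

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on real or synthetic input: per-compartment
#' classified-read descriptives with bootstrap t-tests and post hoc power,
#' Shannon diversity comparison, Bray-Curtis + PCoA + permutation test,
#' Spearman association scan with BH-FDR, and the per-subject oral-to-
#' gastric sharing analysis with group summary, k-distribution, exclusivity
#' calls and co-sharing patterns. All tables are written as TSV into
#' `config$out_dir` together with a markdown summary (`report.md`), the
#' config echo (`config.json`) and a machine-readable run manifest
#' (`manifest.json`). Any stage failure aborts naming the stage.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...,
                                "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e) {
      log_line("FAILED at stage ", name, ": ", conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  res <- list(config = config)
  cfg_json <- file.path(config$out_dir, "config.json")
  echo <- config
  echo$shannon_base <- unclass(echo$shannon_base)
  jsonlite::write_json(lapply(unclass(echo), function(v)
    if (inherits(v, "cohort_params")) unclass(v) else v),
    cfg_json, auto_unbox = TRUE, digits = NA, null = "null")

  if (!is.null(config$synthetic)) {
    gen <- stage("synthetic-generation", {
      pars <- config$synthetic
      pars$seed <- config$seed
      generate_cohort(do.call(cohort_params, unclass(pars)))
    })
    table <- gen$table
    metadata <- gen$metadata
    res$truth <- gen$truth
    stage("synthetic-output", {
      write_count_table(table, file.path(config$out_dir, "counts.tsv"))
      write_metadata(metadata, file.path(config$out_dir, "metadata.tsv"))
      truth_df <- data.frame(subject_id = rownames(gen$truth$seeded)[row(gen$truth$seeded)],
                             translocator = colnames(gen$truth$seeded)[col(gen$truth$seeded)],
                             seeded = as.vector(gen$truth$seeded))
      write_tsv(truth_df, file.path(config$out_dir, "truth_seeding.tsv"))
    })
  } else {
    table <- stage("read-counts", read_count_table(config$input_counts))
    metadata <- stage("read-metadata", read_metadata(config$input_metadata))
  }
  res$table <- table
  res$metadata <- metadata

  pairs <- stage("pairing", build_pairs(metadata, table))
  res$pairs <- pairs

  per_comp <- list()
  for (comp in COMPARTMENTS) {
    per_comp[[comp]] <- stage(paste0("compartment-", comp), {
      ids <- metadata$sample_id[metadata$compartment == comp]
      sub <- subset_samples(table, ids)
      filt <- prevalence_filter(sub, config$prevalence, config$presence_threshold)
      totals <- sample_totals(sub)
      grp <- metadata$group[match(names(totals), metadata$sample_id)]
      desc <- group_descriptives(totals, grp)
      abund_test <- bootstrap_t_test(totals[grp == "case"], totals[grp == "control"],
                                     n_boot = config$n_boot, seed = config$seed + 11L)
      abund_power <- posthoc_power_t(mean(totals[grp == "case"]), stats::sd(totals[grp == "case"]),
                                     sum(grp == "case"),
                                     mean(totals[grp == "control"]), stats::sd(totals[grp == "control"]),
                                     sum(grp == "control"), alpha = config$alpha)
      div <- diversity_by_group(sub, metadata, comp, base = config$shannon_base,
                                n_boot = config$n_boot, seed = config$seed + 13L)
      if (n_taxa(filt) > 0) {
        sub_f <- subset_samples(filt, names(totals)[colSums(filt$counts) > 0])
        bc <- bray_curtis_matrix(sub_f)
        ord <- pcoa(bc, n_axes = 3)
        perm <- permutation_group_test(bc, metadata$group[match(rownames(bc), metadata$sample_id)],
                                       n_perm = config$n_perm, seed = config$seed + 17L)
        assoc <- group_association_scan(filt, metadata, comp,
                                        mode = config$association_mode,
                                        presence_threshold = config$presence_threshold)
      } else {
        # degenerate configuration (e.g. absurd presence threshold): emit
        # empty-but-well-formed downstream outputs instead of aborting
        bc <- NULL; ord <- NULL; perm <- NULL; assoc <- NULL
      }
      list(filtered = filt, totals = totals, descriptives = desc,
           abundance_test = abund_test, abundance_power = abund_power,
           abundance_mw_p = mann_whitney_p(totals[grp == "case"], totals[grp == "control"]),
           diversity = div, distance = bc, pcoa = ord, permanova = perm,
           association = assoc)
    })
  }
  res$compartments <- per_comp

  sharing <- stage("sharing", {
    recs <- sharing_records(pairs, table, config$presence_threshold)
    summ <- sharing_summary(recs)
    list(records = recs, summary = summ,
         top = utils::head(summ, config$top_n),
         dist_case = sharing_distribution(recs, "case"),
         dist_control = sharing_distribution(recs, "control"),
         exclusive = exclusive_taxa(summ),
         co_sharing = co_sharing_patterns(recs))
  })
  res$sharing <- sharing

  stage("write-tables", {
    for (comp in COMPARTMENTS) {
      pc <- per_comp[[comp]]
      write_tsv(pc$diversity$records, file.path(config$out_dir, paste0("diversity_", comp, ".tsv")))
      write_tsv(data.frame(compartment = comp, pc$descriptives),
                file.path(config$out_dir, paste0("abundance_descriptives_", comp, ".tsv")))
      if (!is.null(pc$distance)) {
        d <- as.data.frame(unclass(pc$distance))
        write_tsv(data.frame(sample_id = rownames(pc$distance), d, check.names = FALSE),
                  file.path(config$out_dir, paste0("distance_", comp, ".tsv")))
        co <- as.data.frame(pc$pcoa$coordinates)
        write_tsv(data.frame(sample_id = rownames(pc$pcoa$coordinates), co),
                  file.path(config$out_dir, paste0("pcoa_", comp, ".tsv")))
      }
      a <- if (is.null(pc$association)) {
        data.frame(source = character(0), compartment = character(0),
                   taxon = character(0), rho = character(0), p = character(0),
                   q = character(0), direction = character(0))
      } else {
        pc$association
      }
      if (nrow(a) > 0) {
        a$rho <- fmt_rho(a$rho); a$p <- fmt_p(a$p); a$q <- fmt_p(a$q)
      }
      write_tsv(a, file.path(config$out_dir, paste0("association_", comp, ".tsv")))
    }
    tests <- do.call(rbind, lapply(COMPARTMENTS, function(comp) {
      pc <- per_comp[[comp]]
      data.frame(compartment = comp,
                 variable = c("classified_reads", "shannon"),
                 t = c(pc$abundance_test$t, pc$diversity$test$t),
                 df = c(pc$abundance_test$df, pc$diversity$test$df),
                 p = c(pc$abundance_test$p, pc$diversity$test$p),
                 mann_whitney_p = c(pc$abundance_mw_p, pc$diversity$mann_whitney_p),
                 mean_diff = c(pc$abundance_test$mean_diff, pc$diversity$test$mean_diff),
                 boot_ci_low = c(pc$abundance_test$boot_ci_low, pc$diversity$test$boot_ci_low),
                 boot_ci_high = c(pc$abundance_test$boot_ci_high, pc$diversity$test$boot_ci_high),
                 posthoc_power = c(pc$abundance_power, pc$diversity$power))
    }))
    write_tsv(tests, file.path(config$out_dir, "group_tests.tsv"))
    perm <- do.call(rbind, lapply(COMPARTMENTS, function(comp) {
      pr <- per_comp[[comp]]$permanova
      if (is.null(pr)) return(NULL)
      data.frame(compartment = comp, pseudo_F = pr$pseudo_F, p = pr$p, n_perm = pr$n_perm)
    }))
    if (is.null(perm)) perm <- data.frame(compartment = character(0), pseudo_F = numeric(0),
                                          p = numeric(0), n_perm = integer(0))
    write_tsv(perm, file.path(config$out_dir, "permanova.tsv"))

    top <- sharing$top
    tbl3 <- data.frame(taxon = top$taxon,
                       shared_count_case = top$shared_count_case,
                       shared_pct_case = fmt_pct(top$shared_pct_case),
                       shared_count_control = top$shared_count_control,
                       shared_pct_control = fmt_pct(top$shared_pct_control),
                       pct_diff = fmt_pct(top$pct_diff),
                       rel_diff = ifelse(top$exclusivity == "only-case", "Only CA",
                                         ifelse(top$exclusivity == "only-control", "Only CO",
                                                fmt_pct(top$rel_diff))))
    write_tsv(tbl3, file.path(config$out_dir, "sharing_summary.tsv"))
    write_tsv(data.frame(group = "case", sharing$dist_case),
              file.path(config$out_dir, "sharing_distribution_case.tsv"))
    write_tsv(data.frame(group = "control", sharing$dist_control),
              file.path(config$out_dir, "sharing_distribution_control.tsv"))
    write_tsv(sharing_records_df(sharing$records),
              file.path(config$out_dir, "subject_sharing.tsv"))
  })

  stage("report", {
    md <- c("# Paired oral-gastric microbiome analysis report", "",
            sprintf("- samples: %d (%d subjects paired)", n_samples(table), nrow(pairs)),
            sprintf("- seed: %d; prevalence cut-off: %.3f; presence threshold: %d read(s)",
                    config$seed, config$prevalence, config$presence_threshold), "")
    for (comp in COMPARTMENTS) {
      pc <- per_comp[[comp]]
      dd <- pc$diversity
      md <- c(md, sprintf("## %s", comp),
              sprintf("- taxa retained at %.1f%% prevalence: %d (of %d)",
                      100 * config$prevalence, attr(pc$filtered, "filter")$retained,
                      attr(pc$filtered, "filter")$retained + attr(pc$filtered, "filter")$removed),
              sprintf("- classified reads, case vs control: p = %s (Welch), power = %.2f",
                      fmt_p(pc$abundance_test$p), pc$abundance_power),
              sprintf("- Shannon (base %.3f), case vs control mean: %.2f vs %.2f, p = %s, power = %.2f",
                      config$shannon_base,
                      mean(dd$records$shannon[dd$records$group == "case"]),
                      mean(dd$records$shannon[dd$records$group == "control"]),
                      fmt_p(dd$test$p), dd$power),
              if (is.null(pc$permanova)) {
                "- beta-diversity: skipped (no taxa retained)"
              } else {
                sprintf("- beta-diversity (Bray-Curtis PERMANOVA, %d permutations): pseudo-F = %.3f, p = %s",
                        pc$permanova$n_perm, pc$permanova$pseudo_F, fmt_p(pc$permanova$p))
              }, "")
    }
    excl <- sharing$exclusive
    md <- c(md, "## sharing",
            sprintf("- taxa ever shared: %d; case-exclusive: %d; control-exclusive: %d",
                    nrow(sharing$summary), length(excl$case_only), length(excl$control_only)),
            if (length(excl$case_only) > 0)
              sprintf("- case-exclusive shared taxa: %s", paste(excl$case_only, collapse = ", ")),
            "")
    writeLines(md, file.path(config$out_dir, "report.md"))
  })

  stage("manifest", {
    manifest <- list(package = "gastroshare",
                     package_version = as.character(utils::packageVersion("gastroshare")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."),
                     seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_json)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  })

  log_line("done")
  invisible(res)
}
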