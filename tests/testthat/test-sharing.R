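test_that("presence sets respect the read threshold", {
  v <- c("Genus a" = 0, "Genus b" = 0, "Genus c" = 3)
  expect_equal(presence_set(v), "Genus c")
  expect_equal(presence_set(c(A = 4, B = 5), threshold = 5), "B")
  expect_error(presence_set(v, threshold = 0), "at least 1")
})

test_that("shared taxa are the saliva/biopsy presence intersection", {
  enc <- sets_as_cohort(list(c(GS, PH, SO, SM)), list(character(0)))
  pairs <- build_pairs(enc$metadata, enc$table)
  rec <- shared_taxa(pairs[1, ], enc$table)
  expect_equal(rec$k, 4)
  expect_setequal(rec$shared, c(GS, PH, SO, SM))

  # all-zero biopsy: empty shared set
  m <- matrix(c(5L, 2L, 0L, 0L), 2, 2, dimnames = list(
    c("Genus a", "Genus b"), c("p_SAL", "p_BIO")))
  ct <- count_table(m, warn_empty = FALSE)
  rec0 <- shared_taxa(list(subject_id = "p", group = "case",
                           saliva_sample = "p_SAL", biopsy_sample = "p_BIO"), ct)
  expect_equal(rec0$k, 0)

  # identical supports: shared set equals the full support
  m2 <- matrix(c(5L, 2L, 1L, 7L), 2, 2, dimnames = list(
    c("Genus a", "Genus b"), c("q_SAL", "q_BIO")))
  recF <- shared_taxa(list(subject_id = "q", group = "case",
                           saliva_sample = "q_SAL", biopsy_sample = "q_BIO"),
                      count_table(m2, warn_empty = FALSE))
  expect_setequal(recF$shared, c("Genus a", "Genus b"))
})

test_that("the sharing summary reproduces the published group counts", {
  summ <- sharing_summary(table4_records(), c(case = 20, control = 20))
  so <- summ[summ$taxon == SO, ]
  expect_equal(unlist(so[, 2:7], use.names = FALSE), c(8, 40, 2, 10, 30, 75))
  sm <- summ[summ$taxon == SM, ]
  expect_equal(sm$shared_count_case, 10)
  expect_equal(sm$shared_pct_case, 50)
  expect_equal(sm$rel_diff, 40)
  ph <- summ[summ$taxon == PH, ]
  expect_equal(unlist(ph[, 2:7], use.names = FALSE), c(5, 25, 1, 5, 20, 80))
  gs <- summ[summ$taxon == GS, ]
  expect_equal(gs$shared_count_case, 4)
  expect_equal(gs$shared_pct_case, 20)
  expect_equal(gs$shared_count_control, 0)
  expect_equal(gs$exclusivity, "only-case")
  # layout: pct_diff descending, ties by case count descending
  expect_equal(summ$taxon, c(SO, SM, PH, GS))
  expect_error(sharing_summary(table4_records(), c(case = 0, control = 20)),
               "positive")
})

test_that("rel_diff is undefined when the case share is zero", {
  recs <- records_from_sets(list(character(0)), list("Genus x"))
  summ <- sharing_summary(recs, c(case = 1, control = 1))
  expect_true(is.na(summ$rel_diff))
  expect_equal(summ$exclusivity, "only-control")
})

test_that("the shared-taxa count distribution matches the published k histogram", {
  recs <- table4_records()
  d <- sharing_distribution(recs, "case")
  expect_equal(d$k, 0:4)
  expect_equal(d$count, c(7, 5, 4, 2, 2))
  expect_equal(d$pct, c(35, 25, 20, 10, 10))
  expect_equal(sum(d$count), 20)

  empty <- records_from_sets(replicate(5, character(0), simplify = FALSE), list())
  d0 <- sharing_distribution(empty, "case")
  expect_equal(d0$count, 5)
  expect_equal(d0$k, 0)
})

test_that("exclusive taxa recover the four case-only shared species", {
  summ <- sharing_summary(table3_records(), c(case = 20, control = 20))
  ex <- exclusive_taxa(summ)
  expect_setequal(ex$case_only,
                  c("Fusobacterium pseudoperiodonticum", GS,
                    "Gemella unknown_species", "Veillonella rogosae"))
  expect_equal(length(ex$case_only), 4)
  expect_equal(length(ex$control_only), 0)

  both <- records_from_sets(list("Genus x"), list("Genus x"))
  ex2 <- exclusive_taxa(sharing_summary(both, c(case = 1, control = 1)))
  expect_equal(length(ex2$case_only), 0)
  expect_equal(length(ex2$control_only), 0)
})

test_that("co-sharing flags taxa never shared alone", {
  pat <- co_sharing_patterns(table4_records())
  gs <- pat[pat$taxon == GS, ]
  expect_true(gs$never_alone)
  expect_true(all(gs$partners[[1]] %in% c(SO, SM, PH)))
  so <- pat[pat$taxon == SO, ]
  expect_false(so$never_alone) # SO occurs as a singleton
  expect_equal(nrow(co_sharing_patterns(records_from_sets(list(), list()))), 0)
})

test_that("per-taxon and per-subject tallies agree, with the k identity", {
  set.seed(50)
  g <- generate_cohort(small_params(seed = 61, transloc_prob = 0.5))
  pairs <- build_pairs(g$metadata, g$table)
  recs <- sharing_records(pairs, g$table)
  summ <- sharing_summary(recs)
  # cross-check: per-taxon scan vs per-subject scan
  for (i in seq_len(nrow(summ))) {
    tx <- summ$taxon[i]
    by_subject <- sum(vapply(recs, function(r)
      r$group == "case" && tx %in% r$shared, logical(1)))
    expect_equal(summ$shared_count_case[i], by_subject)
  }
  # sum_k k * n_k == sum of per-taxon shared counts, per group
  for (grp in c("case", "control")) {
    d <- sharing_distribution(recs, grp)
    col <- if (grp == "case") "shared_count_case" else "shared_count_control"
    expect_equal(sum(d$k * d$count), sum(summ[[col]]))
  }
})

test_that("raising the presence threshold never enlarges a shared set", {
  g <- generate_cohort(small_params(seed = 62))
  pairs <- build_pairs(g$metadata, g$table)
  prev <- NULL
  for (thr in c(1, 2, 5, 10)) {
    recs <- sharing_records(pairs, g$table, threshold = thr)
    sets <- lapply(recs, `[[`, "shared")
    if (!is.null(prev)) {
      for (i in seq_along(sets)) expect_true(all(sets[[i]] %in% prev[[i]]))
    }
    prev <- sets
  }
})
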