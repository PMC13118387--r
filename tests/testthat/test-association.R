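test_that("binary group-vs-presence correlation equals 1/3 for a 4-of-20 pattern", {
  x <- rep(c(1, 0), each = 20)
  y <- c(rep(1, 4), rep(0, 36))
  rho <- spearman_with_ties(x, y)
  expect_equal(round(rho, 4), 0.3333)
  expect_equal(rho, 80 / 240) # phi from the 2x2 table
  expect_equal(round(spearman_p(rho, 40), 3), 0.036)
})

test_that("Spearman handles identity, negation symmetry and constant input", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_with_ties(v, v), 1)
  g <- rep(c(1, 0), 4)
  expect_equal(spearman_with_ties(1 - g, v), -spearman_with_ties(g, v))
  expect_warning(r <- spearman_with_ties(rep(2, 5), v[1:5]), "constant")
  expect_true(is.na(r))
})

test_that("midrank Spearman agrees with the stats::cor oracle under ties", {
  set.seed(6)
  for (i in 1:20) {
    x <- rpois(15, 2); y <- rpois(15, 2)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_with_ties(x, y), cor(x, y, method = "spearman"))
  }
})

test_that("Spearman p-values follow the t approximation", {
  expect_equal(spearman_p(0, 40), 1)
  # a printed |rho| = 0.5674 at n = 40 is far below the 3-decimal threshold
  p <- spearman_p(0.5674, 40)
  expect_lt(p, 5e-4); expect_gt(p, 5e-5)
  expect_warning(p1 <- spearman_p(1, 10), "degenerate")
  expect_equal(p1, 0)
  expect_error(spearman_p(0.5, 3), "n >= 4")
})

test_that("binary Spearman equals phi exhaustively over 2x2 tables with margins <= 20/20", {
  x <- rep(c(1, 0), each = 20)
  for (a in 0:20) {
    for (c_ in 0:20) {
      if (a + c_ == 0 || a + c_ == 40) next # constant presence vector
      y <- c(rep(1, a), rep(0, 20 - a), rep(1, c_), rep(0, 20 - c_))
      expect_equal(spearman_with_ties(x, y),
                   phi_coefficient(a, 20 - a, c_, 20 - c_),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH-FDR implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(10)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_equal(q, p.adjust(p, method = "BH")) # independent oracle
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm]) # order does not matter
  pna <- c(0.01, NA, 0.04)
  expect_equal(bh_fdr(pna), c(0.02, NA, 0.04))
})

test_that("the association scan mirrors views and adjusts within compartment", {
  enc <- sets_as_cohort(table4_case_sets(), table4_control_sets())
  scan <- suppressWarnings(
    group_association_scan(enc$table, enc$metadata, "biopsy", mode = "presence"))
  ca <- scan[scan$source == "CA", ]
  co <- scan[scan$source == "CO", ]
  expect_equal(sort(ca$rho), sort(-co$rho))
  m <- merge(ca, co, by = "taxon")
  expect_equal(m$rho.x, -m$rho.y)
  expect_equal(m$p.x, m$p.y)
  expect_true(all(ca$q >= ca$p, na.rm = TRUE))
  expect_true(!is.unsorted(rev(ca$rho), na.rm = TRUE)) # sorted descending
  # GS present in 4 of 20 cases, 0 controls -> the published 1/3 correlation
  expect_equal(round(ca$rho[ca$taxon == GS], 4), 0.3333)
  expect_equal(round(ca$p[ca$taxon == GS], 3), 0.036)
})

test_that("a single-taxon scan has q equal to p", {
  ct <- toy_table(matrix(c(5L, 1L, 0L, 2L, 3L, 1L, 0L, 1L), 1, 8))
  md <- data.frame(sample_id = sample_names(ct),
                   subject_id = paste0("p", 1:8),
                   compartment = "biopsy",
                   group = rep(c("case", "control"), each = 4))
  scan <- group_association_scan(ct, md, "biopsy")
  expect_equal(scan$q, scan$p)
})

test_that("strongly seeded translocators occupy the top case-view positions", {
  # 20 seeded replicates; the spec-level property is >= 90% recovery
  hits <- vapply(1:20, function(s) {
    g <- generate_cohort(cohort_params(transloc_prob = 1, seed = 3000 + s))
    scan <- suppressWarnings(group_association_scan(
      prevalence_filter(subset_samples(g$table,
        g$metadata$sample_id[g$metadata$compartment == "biopsy"]), 0.025),
      g$metadata, "biopsy", mode = "presence"))
    ca <- scan[scan$source == "CA" & !is.na(scan$rho), ]
    top <- head(ca$taxon[order(-ca$rho)], length(g$truth$translocators))
    all(g$truth$translocators %in% top)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("permuting group labels keeps the scan's rejection rate near 5%", {
  g <- generate_cohort(cohort_params(case_biopsy_evenness_penalty = 1,
                                     translocators = 0, seed = 71))
  sal <- prevalence_filter(subset_samples(g$table,
    g$metadata$sample_id[g$metadata$compartment == "saliva"]), 0.025)
  set.seed(99)
  subjects <- unique(g$metadata$subject_id)
  fracs <- vapply(1:40, function(i) {
    md <- g$metadata
    new_grp <- sample(rep(c("case", "control"), each = 20))
    md$group <- new_grp[match(md$subject_id, subjects)]
    scan <- suppressWarnings(group_association_scan(sal, md, "saliva"))
    ca <- scan[scan$source == "CA", ]
    mean(ca$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.09)
})
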