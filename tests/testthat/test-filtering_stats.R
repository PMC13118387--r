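test_that("prevalence filter keeps the right taxa and is idempotent", {
  set.seed(42)
  m <- matrix(rpois(50 * 40, 0.4), 50, 40)
  m[1, ] <- 0 # a taxon seen nowhere
  ct <- toy_table(m)

  ident <- prevalence_filter(ct, 0)
  expect_identical(taxa_names(ident), taxa_names(ct))

  # with 40 samples, the 2.5% rule is "detected in at least one sample"
  f <- prevalence_filter(ct, 0.025)
  expect_identical(taxa_names(f), taxa_names(ct)[rowSums(m >= 1) >= 1])
  expect_false(taxa_names(ct)[1] %in% taxa_names(f))
  expect_equal(attr(f, "filter")$retained + attr(f, "filter")$removed, 50)

  again <- prevalence_filter(f, 0.025)
  expect_identical(again$counts, f$counts)

  expect_error(prevalence_filter(toy_table(matrix(0L, 0, 0)), 0.025), "empty")
})

test_that("sample totals are column sums", {
  ct <- toy_table(matrix(c(3L, 1L, 0L, 2L, 0L, 0L), 2, 3))
  expect_equal(unname(sample_totals(ct)), c(4, 2, 0))
})

test_that("group descriptives match an independent recomputation", {
  expect_equal(group_descriptives(c(1, 2, 3), rep("g", 3))$median, 2)
  expect_equal(group_descriptives(c(1, 2, 3), rep("g", 3))$mean, 2)
  expect_equal(group_descriptives(c(1, 1, 1), rep("g", 3))$sd, 0)
  expect_error(group_descriptives(numeric(0), character(0)), "at least one")

  # oracle: spreadsheet-style recomputation of mean/sd/median/IQR with
  # hand-coded linear interpolation on the sorted values
  interp_quantile <- function(v, q) {
    v <- sort(v); n <- length(v)
    h <- (n - 1) * q + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  set.seed(5)
  v <- round(rlnorm(20, log(159), 1.2))
  d <- group_descriptives(v, rep("case", 20))
  expect_equal(d$n, 20)
  expect_equal(d$mean, sum(v) / 20)
  expect_equal(d$sd, sqrt(sum((v - mean(v))^2) / 19))
  expect_equal(d$median, interp_quantile(v, 0.5))
  expect_equal(d$iqr_low, interp_quantile(v, 0.25))
  expect_equal(d$iqr_high, interp_quantile(v, 0.75))
  expect_true(d$iqr_low <= d$median && d$median <= d$iqr_high)
})

test_that("bootstrap t-test handles identity, degeneracy, and is reproducible", {
  x <- c(1, 2, 3, 4, 5)
  r <- bootstrap_t_test(x, x, n_boot = 100, seed = 1)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$mean_diff, 0)

  expect_warning(rd <- bootstrap_t_test(rep(2, 4), rep(2, 4), n_boot = 50, seed = 1),
                 "identical")
  expect_equal(rd$p, 1)

  a <- rnorm(10); b <- rnorm(10)
  r1 <- bootstrap_t_test(a, b, n_boot = 200, seed = 9)
  r2 <- bootstrap_t_test(a, b, n_boot = 200, seed = 9)
  expect_identical(r1, r2)
  r3 <- bootstrap_t_test(a, b, n_boot = 500, seed = 9)
  # widening n_boot never changes the point estimates
  expect_equal(r3$t, r1$t)
  expect_equal(r3$p, r1$p)
  expect_equal(r3$mean_diff, r1$mean_diff)
  expect_lte(r1$boot_ci_low, r1$boot_ci_high)

  # Welch statistic agrees with the reference implementation
  tt <- t.test(a, b)
  expect_equal(r1$t, unname(tt$statistic))
  expect_equal(r1$p, tt$p.value)
})

test_that("bootstrap t-test holds its type-I error under the null", {
  # 600 null replicates (scaled down from a larger simulation for runtime)
  set.seed(314)
  n_rep <- 600
  rej <- mean(vapply(seq_len(n_rep), function(i) {
    bootstrap_t_test(rnorm(15), rnorm(15), n_boot = 5, seed = i)$p < 0.05
  }, logical(1)))
  band <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rej, 0.05 - band)
  expect_lt(rej, 0.05 + band)
})

test_that("post hoc power: null effect, saturation, monotonicity", {
  expect_equal(posthoc_power_t(5, 1, 20, 5, 1, 20), 0.05, tolerance = 1e-9)
  expect_gt(posthoc_power_t(5, 1, 20, 0, 1, 20), 0.999) # d = 5
  p1 <- posthoc_power_t(1, 2, 15, 0, 2, 15)
  p2 <- posthoc_power_t(2, 2, 15, 0, 2, 15)
  expect_lt(p1, p2)
  expect_lt(posthoc_power_t(1, 2, 10, 0, 2, 10), posthoc_power_t(1, 2, 40, 0, 2, 40))
  expect_error(posthoc_power_t(1, 0, 10, 0, 1, 10), "positive")
})

test_that("post hoc power matches a Monte-Carlo oracle at the observed effect", {
  # observed case/control classified-read abundances: mean 325.4 (sd 305.3)
  # vs 160.1 (sd 149.7), n = 20 each
  pw <- posthoc_power_t(325.4, 305.3, 20, 160.1, 149.7, 20, alpha = 0.05)
  expect_gte(pw, 0); expect_lte(pw, 1)

  # 100k simulated pooled-variance t-tests under that effect, vectorized
  set.seed(2718)
  nsim <- 100000; n <- 20
  sp <- sqrt((305.3^2 + 149.7^2) / 2)
  x <- matrix(rnorm(nsim * n, 325.4, sp), nsim)
  y <- matrix(rnorm(nsim * n, 160.1, sp), nsim)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1); vy <- rowSums((y - my)^2) / (n - 1)
  sp2 <- (vx + vy) / 2
  tstat <- (mx - my) / sqrt(sp2 * 2 / n)
  mc <- mean(abs(tstat) > qt(0.975, 2 * n - 2))
  expect_equal(pw, mc, tolerance = 0.01)
})

test_that("pooled-variance option reduces to the classical t-test", {
  set.seed(8)
  a <- rnorm(12); b <- rnorm(9, 0.5)
  r <- bootstrap_t_test(a, b, n_boot = 50, seed = 2, var_equal = TRUE)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$df, unname(tt$parameter))
  expect_equal(r$p, tt$p.value)
})
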