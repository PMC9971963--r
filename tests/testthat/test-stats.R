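test_that("exact signed-rank p-values match full enumeration", {
  # all-positive differences, n = 6: W = 0, p = 2/2^6
  d <- c(0.4, 1.1, 0.2, 0.9, 1.5, 0.7)
  r <- wilcoxon_signed_rank(differences = d)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.03125)
  expect_equal(r$method, "exact")
  # antisymmetric differences: W+ = W-, p = 1
  r2 <- wilcoxon_signed_rank(differences = c(0.5, -0.5, 1.2, -1.2))
  expect_equal(r2$p_value, 1)
  # random instances (with ties and zeros) vs the enumeration oracle
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- round(stats::rnorm(n), sample(0:2, 1))
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(differences = d)$p_value,
                 oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # sign flip invariance; zeros dropped; degenerate error
  d <- c(0.3, -0.8, 0, 1.4, 0.2)
  expect_equal(wilcoxon_signed_rank(differences = d)$p_value,
               wilcoxon_signed_rank(differences = -d)$p_value)
  expect_equal(wilcoxon_signed_rank(differences = d)$n_effective, 4)
  expect_error(wilcoxon_signed_rank(differences = c(0, 0)), "degenerate")
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  # complete separation at the study group sizes: U = 0, one-sided 1/C(20,7)
  a <- seq_len(7); b <- 7 + seq_len(13)
  r <- mann_whitney_u(a, b, alternative = "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / choose(20, 7), tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # identical groups: U = nA nB / 2, p = 1
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 4.5)
  expect_equal(r2$p_value, 1)
  # label symmetry: swapping groups preserves U = min and p
  set.seed(202)
  for (i in 1:40) {
    nA <- sample(3:6, 1); nB <- sample(3:6, 1)
    a <- round(stats::rnorm(nA), 1); b <- round(stats::rnorm(nB), 1)
    pa <- mann_whitney_u(a, b)
    pb <- mann_whitney_u(b, a)
    expect_equal(pa$p_value, pb$p_value, tolerance = 1e-12)
    expect_equal(pa$statistic, pb$statistic)
    expect_equal(pa$U_A + pa$U_B, nA * nB)
    expect_equal(pa$p_value, oracle_mann_whitney_p(a, b), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Friedman test matches base R, its maximal statistic, and its exact path", {
  # identical rankings across n = 10 subjects, k = 3: statistic 2n = 20
  X <- t(apply(matrix(stats::rnorm(30), 10, 3), 1, sort))
  f <- friedman_test(X)
  expect_equal(f$statistic, 20)
  expect_lt(f$p_value, 0.001)
  # constant rows: all midranks, statistic 0, p 1
  fc <- friedman_test(matrix(1, 5, 3))
  expect_equal(fc$statistic, 0)
  expect_equal(fc$p_value, 1)
  # agreement with stats::friedman.test incl. ties
  set.seed(303)
  for (i in 1:15) {
    X <- matrix(round(stats::rnorm(36), 1), 12, 3)
    f1 <- friedman_test(X)
    f2 <- stats::friedman.test(X)
    expect_equal(f1$statistic, unname(f2$statistic), tolerance = 1e-12)
    expect_equal(f1$p_value, unname(f2$p.value), tolerance = 1e-12)
  }
  # exact path: valid p, consistent with Monte Carlo permutation at small n
  set.seed(304)
  X <- matrix(stats::rnorm(15), 5, 3)
  fe <- friedman_test(X, exact = TRUE)
  expect_true(fe$p_value >= 0 && fe$p_value <= 1)
  obs <- friedman_test(X)$statistic
  mc <- replicate(4000, {
    Xp <- t(apply(X, 1, sample))
    friedman_test(Xp)$statistic
  })
  p_mc <- mean(mc >= obs - 1e-9)
  expect_lt(abs(fe$p_value - p_mc), 0.04)
  expect_error(friedman_test(matrix(1, 5, 2)), "3 conditions")
})

test_that("pairwise Wilcoxon follow-ups recover a constructed location contrast", {
  set.seed(404)
  n <- 15
  asc <- stats::rnorm(n, 100, 5)
  arch <- stats::rnorm(n, 70, 5)
  desc <- stats::rnorm(n, 69, 5)
  res <- pairwise_wilcoxon_after_friedman(cbind(asc = asc, arch = arch,
                                                desc = desc))
  expect_equal(nrow(res), 3)
  expect_lt(res$p_value[res$pair == "asc vs arch"], 0.01)
  expect_lt(res$p_value[res$pair == "asc vs desc"], 0.01)
  expect_gt(res$p_value[res$pair == "arch vs desc"], 0.05)
  # identical columns: degenerate pairs flagged with p = 1
  same <- matrix(rep(stats::rnorm(6), 3), ncol = 3)
  res2 <- pairwise_wilcoxon_after_friedman(same)
  expect_true(all(res2$degenerate))
  expect_true(all(res2$p_value == 1))
  # Bonferroni column on request
  res3 <- pairwise_wilcoxon_after_friedman(cbind(asc, arch, desc),
                                           bonferroni = TRUE)
  expect_equal(res3$p_bonferroni, pmin(1, res3$p_value * 3))
})

test_that("chi-square test matches hand computation and flags small cells", {
  r <- chi_square_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # [[10,0],[0,10]]: all expected 5, statistic sum((O-E)^2/E) = 20, df 1
  r2 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1)
  expect_false(r2$small_expected)
  # a sparse table trips the small-expected-count warning
  expect_warning(r3 <- chi_square_test(matrix(c(3, 1, 1, 3), 2)),
                 "expected")
  expect_true(r3$small_expected)
  # transposition invariance
  set.seed(505)
  tb <- matrix(rpois(4, 8) + 5, 2)
  expect_equal(chi_square_test(tb)$statistic,
               chi_square_test(t(tb))$statistic, tolerance = 1e-12)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("synthetic cohorts are reproducible and carry constructed effects", {
  spec <- cohort_spec(seed = 11)
  t1 <- generate_cohort_table(spec)
  t2 <- generate_cohort_table(spec)
  expect_identical(t1, t2)
  expect_equal(sort(unique(t1$group)), c("NOP", "OP"))
  expect_equal(nrow(t1), (7 + 13) * 2 * 2)
  # a 1-SD OP follow-up decrease shows up in the OP paired differences
  m <- default_cohort_measurements()
  m$wss_outer_ascending$fu_effect_sd <- c(OP = -1, NOP = 0)
  eff <- generate_cohort_table(cohort_spec(measurements = m, seed = 12))
  w <- eff[eff$measurement_name == "wss_outer_ascending" &
             eff$group == "OP", ]
  b <- w$value[w$timepoint == "B"]; fu <- w$value[w$timepoint == "FU"]
  expect_lt(mean(fu - b), 0)
})
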