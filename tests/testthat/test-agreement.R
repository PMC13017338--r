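test_that("percent predicted is the measured/predicted ratio with floor display", {
  pp <- percent_predicted(3560, 5209.9)
  expect_equal(pp, 3560 / 5209.9 * 100, tolerance = 1e-12)
  expect_equal(display_percent(pp), 68L)
  expect_equal(display_percent(percent_predicted(3560, 3105.3)), 114L)
  expect_equal(percent_predicted(2500, 2500), 100)
  expect_error(percent_predicted(2500, 0), "positive")
  expect_error(percent_predicted(-1, 100), "positive")
})

test_that("capacity classification is inclusive at the threshold and uses the continuous value", {
  expect_equal(classify_capacity(80), "normal")
  expect_equal(classify_capacity(79.99), "reduced")
  expect_equal(classify_capacity(68.33), "reduced")
  expect_equal(classify_capacity(c(50, 80, 120), threshold = 80),
               c("reduced", "normal", "normal"))
  # monotone flip as the prediction crosses measured*100/threshold
  m <- 2400; t <- 80
  crossing <- m * 100 / t
  expect_equal(classify_capacity(percent_predicted(m, crossing - 1), t), "normal")
  expect_equal(classify_capacity(percent_predicted(m, crossing), t), "normal")
  expect_equal(classify_capacity(percent_predicted(m, crossing + 1), t), "reduced")
})

test_that("Cohen's kappa matches hand-worked cases and degenerate conventions", {
  x <- c("normal", "normal", "reduced", "reduced")
  y <- c("normal", "reduced", "reduced", "reduced")
  expect_equal(cohens_kappa(x, y), 0.5)           # po=.75, pe=.5
  expect_equal(cohens_kappa(x, x), 1)
  expect_equal(cohens_kappa(rep("normal", 5), rep("reduced", 5)), 0)
  expect_equal(cohens_kappa(rep("normal", 5), rep("normal", 5)), 1)
  expect_error(cohens_kappa(x, y[1:3]), "equal length")
})

test_that("kappa is symmetric, bounded and permutation invariant", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    a <- sample(c("normal", "reduced"), n, replace = TRUE)
    b <- sample(c("normal", "reduced"), n, replace = TRUE)
    k <- cohens_kappa(a, b)
    expect_gte(k, -1); expect_lte(k, 1)
    expect_equal(k, cohens_kappa(b, a), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(k, cohens_kappa(a[perm], b[perm]), tolerance = 1e-12)
  }
})

test_that("kappa bands are half-open and match the conventional labels", {
  expect_equal(kappa_band(0.51), "moderate")
  expect_equal(kappa_band(0.78), "substantial")
  expect_equal(kappa_band(0.90), "almost perfect")
  expect_equal(kappa_band(c(-0.2, 0.005, 0.01, 0.21, 0.41, 0.61, 0.81, 1)),
               c("none", "none", "slight", "fair", "moderate", "substantial",
                 "almost perfect", "almost perfect"))
})

test_that("reclassification counts both directions and is symmetric across pair order", {
  r0 <- reclassification(c(70, 90, 85), c(70, 90, 85))
  expect_equal(c(r0$n_to_normal, r0$n_to_reduced, r0$fraction_reclassified),
               c(0, 0, 0))
  r <- reclassification(c(70, 90), c(85, 75))
  expect_equal(r$n_to_normal, 1L)
  expect_equal(r$n_to_reduced, 1L)
  expect_equal(r$fraction_reclassified, 1)
  # threshold 0.001: everyone normal under both (threshold must be > 0)
  r2 <- reclassification(c(10, 20, 30), c(1, 2, 3), threshold = 0.001)
  expect_equal(r2$fraction_reclassified, 0)
  set.seed(7)
  for (i in 1:20) {
    a <- runif(30, 40, 130); b <- runif(30, 40, 130)
    expect_equal(reclassification(a, b)$n_to_normal,
                 reclassification(b, a)$n_to_reduced)
  }
  expect_error(reclassification(1:3, 1:2), "equal length")
})

test_that("absolute-difference quartiles use linear interpolation", {
  z <- absolute_difference_summary(c(80, 90, 100), c(80, 90, 100))
  expect_equal(c(z$ad_median, z$ad_q1, z$ad_q3), c(0, 0, 0))
  expect_equal(absolute_difference_summary(c(80, 90), c(70, 95))$ad_median, 7.5)
  z2 <- absolute_difference_summary(c(10, 20, 30, 40), c(0, 0, 0, 0))
  expect_equal(c(z2$ad_q1, z2$ad_median, z2$ad_q3), c(17.5, 25, 32.5))
  expect_true(z2$ad_q1 <= z2$ad_median && z2$ad_median <= z2$ad_q3)
})

test_that("Friedman statistic matches hand-worked and oracle values", {
  # identical columns: no evidence of differences
  m0 <- matrix(rep(c(70, 80, 90, 100), 3), ncol = 3)
  f0 <- friedman_test(m0)
  expect_equal(f0$chi2, 0)
  expect_equal(f0$kendall_w, 0)
  # perfectly concordant 3x3: rank sums (3,6,9)
  m1 <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), ncol = 3)
  f1 <- friedman_test(m1)
  expect_equal(f1$chi2, 6)
  expect_equal(f1$kendall_w, 1)
  expect_equal(f1$df, 2L)
  # random matrices vs the independent pairwise-comparison oracle
  set.seed(23)
  for (i in 1:25) {
    m <- matrix(rnorm(20 * 6), 20, 6)
    expect_equal(friedman_test(m)$chi2, friedman_oracle(m), tolerance = 1e-10)
  }
  # tie-free matrices agree with the reference implementation in stats
  set.seed(29)
  for (i in 1:10) {
    m <- matrix(rnorm(15 * 4), 15, 4)
    expect_equal(friedman_test(m)$chi2,
                 unname(stats::friedman.test(m)$statistic), tolerance = 1e-10)
  }
  expect_error(friedman_test(matrix(1, 5, 2)), "at least")
  mna <- matrix(rnorm(12), 4, 3); mna[2, 2] <- NA
  expect_error(friedman_test(mna), "missing")
})

test_that("Friedman is invariant to increasing transforms of a row and W stays in [0,1]", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rnorm(12 * 5), 12, 5)
    f <- friedman_test(m)
    expect_gte(f$kendall_w, 0); expect_lte(f$kendall_w, 1)
    m2 <- m
    m2[3, ] <- exp(m2[3, ])  # strictly increasing transform of one row
    expect_equal(friedman_test(m2)$chi2, f$chi2, tolerance = 1e-10)
  }
  # W = 1 only under identical tie-free within-row orderings
  m <- matrix(rep(c(5, 1, 3, 2), each = 8), 8, 4)
  expect_equal(friedman_test(m)$kendall_w, 1)
})

test_that("effect size from the printed cohort statistics is internally consistent", {
  expect_equal(round(kendall_w(936.0, 305, 6), 1), 0.6)
})

test_that("post hoc reports all pairs with Bonferroni-capped p-values", {
  set.seed(41)
  m <- matrix(rnorm(30 * 6, mean = rep(1:6, each = 30)), 30, 6,
              dimnames = list(NULL, letters[1:6]))
  ph <- pairwise_posthoc(m)
  expect_equal(nrow(ph), 15L)
  expect_true(all(ph$p_adj <= 1) && all(ph$p_adj >= ph$p_raw))
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 15))
  # identical columns: all p = 1 by convention
  m0 <- matrix(rep(rnorm(10), 3), 10, 3)
  expect_true(all(pairwise_posthoc(m0)$p_adj == 1))
  # raw p >= 1/15 is capped
  set.seed(43)
  mnull <- matrix(rnorm(10 * 6), 10, 6)
  phn <- pairwise_posthoc(mnull)
  expect_true(any(phn$p_adj == 1))
})
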