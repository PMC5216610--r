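test_that("the 32-joint ordinal score summarises as sum over evaluated joints", {
  all5 <- larsen_assessment(rep(5L, 32))
  expect_equal(sum(all5$joint_scores), 160)
  expect_equal(larsen_mean(all5), 5.0)
  expect_true(all5$erosions_present)

  expect_equal(larsen_mean(larsen_assessment(rep(0L, 32))), 0.0)
  half <- larsen_assessment(c(rep(3L, 16), rep(NA, 16)))
  expect_equal(larsen_mean(half), 3.0)
  expect_equal(sum(half$evaluated), 16)

  ones <- larsen_assessment(rep(1L, 32))
  expect_false(ones$erosions_present)
  expect_true(larsen_assessment(c(2L, rep(0L, 31)))$erosions_present)

  expect_error(larsen_assessment(rep(2L, 10)), class = "dxr_larsen_error")
  expect_error(larsen_assessment(rep(6L, 32)), class = "dxr_larsen_error")
  expect_error(larsen_assessment(rep(NA_integer_, 32)),
               class = "dxr_larsen_error")
})

test_that("pearson_r matches hand-computed values and is affine invariant", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  set.seed(4)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearson_r(3.2 * a + 7, b), pearson_r(a, b), tolerance = 1e-12)
  expect_equal(pearson_r(a, -2 * b), -pearson_r(a, b), tolerance = 1e-12)
  expect_error(pearson_r(a, rep(1, 50)),
               class = "dxr_undefined_correlation_error")
  expect_error(pearson_r(1:5, 1:4), class = "dxr_stat_error")
})

test_that("bootstrap comparison is deterministic and sane for identical methods", {
  set.seed(9)
  x <- rnorm(49); y <- 0.7 * x + rnorm(49, 0, 0.5)
  b1 <- bootstrap_compare_correlations(x, y, y, reps = 1000, seed = 12)
  expect_equal(b1$diff, 0)
  expect_gte(b1$p_value, 0.95)
  b2 <- bootstrap_compare_correlations(x, y, y, reps = 1000, seed = 12)
  expect_identical(b1, b2)

  yB <- 0.7 * x + rnorm(49, 0, 0.5)
  b3 <- bootstrap_compare_correlations(x, y, yB, reps = 1000, seed = 12)
  expect_gte(b3$critical_diff, 0)
  expect_true(b3$p_value >= 0 && b3$p_value <= 1)
  expect_error(bootstrap_compare_correlations(x, y, yB, reps = 100, seed = 1),
               class = "dxr_stat_error")
})

test_that("group contrasts and paired agreement match closed forms", {
  v <- c(rep(7.6, 10), rep(10, 12))
  f <- c(rep(TRUE, 10), rep(FALSE, 12))
  expect_equal(group_percent_difference(v, f), -24.0)
  expect_equal(group_percent_difference(v, !f), 100 * (10 - 7.6) / 7.6)
  expect_equal(group_percent_difference(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, FALSE)),
               -50)
  expect_equal(group_percent_difference(c(2, 2, 1, 1), c(TRUE, TRUE, FALSE, FALSE)),
               100)
  expect_equal(group_percent_difference(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE)),
               0)
  expect_error(group_percent_difference(v, rep(TRUE, 22)),
               class = "dxr_stat_error")

  a <- c(4, 5, 6)
  expect_equal(paired_agreement_sd_percent(a, a), 0)
  expect_equal(paired_agreement_sd_percent(a + 2, a), 0)  # constant offset
  set.seed(6)
  base <- rep(10, 1e4)
  noisy <- base + rnorm(1e4, 0, 0.02 * 10)
  expect_equal(paired_agreement_sd_percent(noisy, base), 2.0, tolerance = 0.05)
  expect_error(paired_agreement_sd_percent(c(-1, 0, 1), c(1, 0, -1)),
               class = "dxr_stat_error")
})

test_that("threshold classification matches the analytic normal overlap", {
  expect_equal(sum(erosion_threshold_classify(c(5, 6, 7), 4)$flags), 0)
  expect_equal(sum(erosion_threshold_classify(c(5, 6, 7), -Inf)$flags), 0)

  set.seed(13)
  n <- 4000
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  mci <- c(rnorm(n / 2, 0.32, 0.04), rnorm(n / 2, 0.42, 0.04))
  thr <- 0.37
  res <- erosion_threshold_classify(mci, thr, truth)
  # analytic misclassification of the equal-weight two-Gaussian mixture
  p_true <- 0.5 * stats::pnorm(thr, 0.32, 0.04, lower.tail = FALSE) +
            0.5 * stats::pnorm(thr, 0.42, 0.04)
  ci <- stats::qbinom(c(0.0005, 0.9995), n, p_true) / n
  expect_gte(res$misclassification_rate, ci[1])
  expect_lte(res$misclassification_rate, ci[2])
  expect_equal(res$tp + res$fn, n / 2)
  expect_equal(res$tn + res$fp, n / 2)
})
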