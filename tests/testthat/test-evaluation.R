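test_that("empirical AUROC matches the exhaustive pairwise oracle", {
  expect_identical(empirical_auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(empirical_auroc(c(5, 5), c(0, 1)), 0.5)
  s <- c(1, 3, 2, 4, 4)
  y <- c(0, 0, 1, 1, 0)
  expect_equal(empirical_auroc(s, y), bf_auroc(s, y))

  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    scores <- sample(0:12, n, replace = TRUE)
    outcomes <- rbinom(n, 1, 0.3)
    if (sum(outcomes) == 0 || sum(outcomes) == n) next
    expect_equal(empirical_auroc(scores, outcomes), bf_auroc(scores, outcomes))
  }
  expect_error(empirical_auroc(c(1, 2), c(1, 1)), "degenerate")
})

test_that("AUROC is invariant to monotone transforms and flips with labels", {
  set.seed(7)
  scores <- rnorm(150)
  outcomes <- rbinom(150, 1, 0.4)
  a <- empirical_auroc(scores, outcomes)
  expect_equal(empirical_auroc(exp(scores), outcomes), a)
  expect_equal(empirical_auroc(2 * scores + 5, outcomes), a)
  expect_equal(empirical_auroc(scores, 1 - outcomes), 1 - a)
})

test_that("DeLong variance agrees with the placement-value oracle and pROC", {
  set.seed(11)
  scores <- sample(0:8, 10, replace = TRUE)
  outcomes <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0)
  ra <- delong_ci(scores, outcomes)
  expect_equal(ra$auroc, empirical_auroc(scores, outcomes))
  expect_equal(ra$delong_variance, bf_delong_var(scores, outcomes))

  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- sample(0:15, 400, replace = TRUE)
  outcomes <- rbinom(400, 1, plogis(-2 + 0.2 * scores))
  ra <- delong_ci(scores, outcomes)
  pr <- pROC::roc(outcomes, scores, quiet = TRUE, direction = "<")
  expect_equal(ra$auroc, as.numeric(pROC::auc(pr)))
  expect_equal(ra$delong_variance, as.numeric(pROC::var(pr, method = "delong")))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(ra$ci_low, ra$ci_high), ci[c(1, 3)])
})

test_that("perfect separation gives variance zero and a degenerate interval", {
  ra <- delong_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_identical(ra$auroc, 1)
  expect_identical(ra$delong_variance, 0)
  expect_identical(c(ra$ci_low, ra$ci_high), c(1, 1))
})

test_that("the paired DeLong test is antisymmetric and matches the covariance oracle", {
  set.seed(13)
  outcomes <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 1)
  a <- sample(0:10, 12, replace = TRUE)
  b <- pmin(10, a + sample(-2:2, 12, replace = TRUE))

  self <- delong_paired_test(a, a, outcomes)
  expect_identical(self$z_statistic, 0)
  expect_identical(self$p_value, 1)

  ab <- delong_paired_test(a, b, outcomes)
  ba <- delong_paired_test(b, a, outcomes)
  expect_equal(ab$z_statistic, -ba$z_statistic)
  expect_equal(ab$p_value, ba$p_value)

  var_diff <- bf_delong_var(a, outcomes) + bf_delong_var(b, outcomes) -
    2 * bf_delong_cov(a, b, outcomes)
  z_oracle <- (bf_auroc(a, outcomes) - bf_auroc(b, outcomes)) / sqrt(var_diff)
  expect_equal(ab$z_statistic, z_oracle)

  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rbinom(300, 1, 0.3)
  s1 <- rnorm(300) + y
  s2 <- rnorm(300) + 0.5 * y
  ours <- delong_paired_test(s1, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$z_statistic, as.numeric(ref$statistic))
  expect_equal(ours$p_value, as.numeric(ref$p.value))
})

test_that("threshold tables equal a brute-force recount at every cutoff", {
  scores <- c(3, 1, 4, 4, 2, 5, 1, 3)
  outcomes <- c(0, 0, 1, 0, 0, 1, 0, 1)
  tab <- threshold_table(scores, outcomes)
  expect_identical(tab$cutoff, sort(unique(scores)))
  for (i in seq_len(nrow(tab))) {
    oracle <- bf_threshold_row(scores, outcomes, tab$cutoff[i])
    expect_equal(unlist(tab[i, -1]), oracle)
  }
  expect_equal(tab$youden_j, tab$sensitivity + tab$specificity - 1)

  # lowest cutoff classifies everyone high risk
  expect_identical(tab$sensitivity[1], 1)
  expect_identical(tab$proportion_high_risk[1], 1)
  expect_equal(tab$observed_cfr_high_risk[1], mean(outcomes))

  # sensitivity never increases, specificity never decreases along cutoffs
  set.seed(15)
  scores <- sample(0:20, 300, replace = TRUE)
  outcomes <- rbinom(300, 1, 0.2)
  tab <- threshold_table(scores, outcomes)
  expect_true(all(diff(tab$sensitivity) <= 1e-12))
  expect_true(all(diff(tab$specificity) >= -1e-12))
})

test_that("the optimal cutoff maximizes Youden J with ties broken downward", {
  tab <- threshold_table(c(1, 2, 3, 4), c(0, 0, 1, 1))
  best <- optimal_cutoff(tab)
  expect_identical(best$cutoff, 3)
  expect_identical(best$youden_j, 1)

  tied <- tibble::tibble(cutoff = c(2, 5, 7),
                         sensitivity = c(0.9, 0.8, 0.7),
                         specificity = c(0.3, 0.4, 0.5),
                         youden_j = c(0.2, 0.2, 0.2),
                         proportion_high_risk = c(0.9, 0.5, 0.2),
                         observed_cfr_high_risk = c(0.1, 0.15, 0.2))
  expect_identical(optimal_cutoff(tied)$cutoff, 2)

  set.seed(16)
  scores <- sample(0:12, 200, replace = TRUE)
  outcomes <- rbinom(200, 1, plogis(-2 + 0.3 * scores))
  tab <- threshold_table(scores, outcomes)
  expect_identical(optimal_cutoff(tab)$cutoff,
                   tab$cutoff[which.max(tab$youden_j)])
})

test_that("stratified analysis runs per stratum and reports skips", {
  set.seed(17)
  scores <- sample(0:10, 120, replace = TRUE)
  outcomes <- rbinom(120, 1, plogis(-2 + 0.3 * scores))
  doubled <- stratified_auroc(c(scores, scores), c(outcomes, outcomes),
                              rep(c("x", "y"), each = 120))
  expect_equal(doubled$auroc[1], doubled$auroc[2])

  strata <- rep(c("young", "old"), each = 60)
  outcomes2 <- outcomes
  outcomes2[strata == "old"] <- 0
  res <- stratified_auroc(scores, outcomes2, strata)
  old_row <- res[res$stratum == "old", ]
  expect_true(old_row$skipped)
  expect_match(old_row$reason, "outcome class")
  expect_false(res[res$stratum == "young", ]$skipped)

  # pooled AUROC can reverse the within-stratum signal
  s1 <- c(1, 2)
  y1 <- c(0, 1)
  s2 <- c(11, 12)
  y2 <- c(0, 1)
  pooled <- empirical_auroc(c(s1, 5, s2, 6), c(y1, 1, y2, 0))
  within <- empirical_auroc(s1, y1)
  expect_identical(within, 1)
  expect_lt(pooled, 1)
})

test_that("discrimination bands follow the published interpretation thresholds", {
  expect_identical(discrimination_band(0.83), "good")
  expect_identical(discrimination_band(0.70), "acceptable")
  expect_identical(discrimination_band(0.49), "none")
  expect_identical(discrimination_band(c(0.5, 0.69, 0.79, 0.8, 0.9, 1.0)),
                   c("poor", "poor", "acceptable", "good", "excellent",
                     "excellent"))
  expect_error(discrimination_band(1.2), "\\[0, 1\\]")
})

test_that("a score independent of outcome yields a null AUROC with covering CI", {
  set.seed(18)
  scores <- c(rnorm(2000), rnorm(2000))
  outcomes <- rep(c(1, 0), each = 2000)
  ra <- delong_ci(scores, outcomes)
  expect_gt(ra$auroc, 0.45)
  expect_lt(ra$auroc, 0.55)
  expect_lte(ra$ci_low, 0.5)
  expect_gte(ra$ci_high, 0.5)
})
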