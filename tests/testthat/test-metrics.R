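test_that("confusion metrics follow their definitions and flag undefined ones", {
  m <- confusion_metrics(confusion_counts(45, 5, 5, 45))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$accuracy, 0.9)

  perfect <- confusion_metrics(confusion_counts(50, 0, 0, 50))
  expect_true(all(perfect == 1))

  und <- confusion_metrics(confusion_counts(0, 0, 10, 90))
  expect_true(is.na(und$precision))
  expect_equal(und$specificity, 1)

  expect_error(confusion_counts(0, 0, 0, 0), "positive")
  expect_error(confusion_counts(-1, 0, 0, 5), "non-negative")
})

test_that("Cohen's kappa matches the closed form and a label-vector oracle", {
  k <- cohens_kappa(confusion_counts(45, 5, 5, 45))
  expect_equal(k$kappa, 0.8)
  expect_equal(k$landis_koch_label, "substantial")

  # brute-force oracle: expand the table into label vectors and count
  pred <- c(rep(1, 45), rep(1, 5), rep(0, 5), rep(0, 45))
  truth <- c(rep(1, 45), rep(0, 5), rep(1, 5), rep(0, 45))
  p_o <- mean(pred == truth)
  p_e <- mean(pred) * mean(truth) + mean(!pred) * mean(!truth)
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))

  # perfect balanced agreement
  expect_equal(cohens_kappa(confusion_counts(50, 0, 0, 50))$kappa, 1)
  expect_equal(cohens_kappa(confusion_counts(50, 0, 0, 50))$landis_koch_label,
               "almost_perfect")

  # constant predictor scores zero
  expect_equal(cohens_kappa(confusion_counts(60, 40, 0, 0))$kappa, 0)

  # degenerate marginals are undefined, not zero
  expect_true(is.na(cohens_kappa(confusion_counts(100, 0, 0, 0))$kappa))

  # identity property at arbitrary class balance
  withr::with_seed(3, {
    for (i in 1:5) {
      tp <- sample(1:50, 1); tn <- sample(1:50, 1)
      expect_equal(cohens_kappa(confusion_counts(tp, 0, 0, tn))$kappa, 1)
    }
  })
})

test_that("Landis-Koch bands are closed on their upper edges", {
  expect_equal(landis_koch(-0.1), "poor")
  expect_equal(landis_koch(0.0), "slight")
  expect_equal(landis_koch(0.20), "slight")
  expect_equal(landis_koch(0.21), "fair")
  expect_equal(landis_koch(0.40), "fair")
  expect_equal(landis_koch(0.41), "moderate")
  expect_equal(landis_koch(0.60), "moderate")
  expect_equal(landis_koch(0.61), "substantial")
  expect_equal(landis_koch(0.72), "substantial")
  expect_equal(landis_koch(0.80), "substantial")
  expect_equal(landis_koch(0.81), "almost_perfect")
  expect_equal(landis_koch(1.0), "almost_perfect")
})

test_that("Spearman correlation equals rank-then-Pearson and base R", {
  expect_equal(spearman_cor(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(6, 4, 2))$rho, -1)

  withr::with_seed(7, {
    for (i in 1:10) {
      x <- rnorm(20); y <- rnorm(20)
      r <- spearman_cor(x, y)
      oracle <- cor(rank(x), rank(y))
      expect_equal(r$rho, oracle, tolerance = 1e-12)
      expect_equal(r$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
      # invariance under strictly monotone transforms
      expect_equal(spearman_cor(exp(x), y^3)$rho, r$rho, tolerance = 1e-12)
      expect_equal(spearman_cor(exp(x), atan(y))$rho, r$rho,
                   tolerance = 1e-12)
    }
  })

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("small-sample Spearman p-values match exact enumeration in base R", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- rnorm(6); y <- rnorm(6)
      r <- spearman_cor(x, y)
      expect_equal(r$method, "exact permutation")
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = TRUE, alternative = "two.sided"))
      expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
    }
  })
})

test_that("rank-sum statistic matches enumeration and wilcox.test; d is calibrated", {
  a <- c(1.2, 3.4, 2.2); b <- c(0.5, 4.0, 0.9)
  r <- ranksum_and_effect(a, b)
  # brute-force U: count of (a_i, b_j) pairs with a_i > b_j (+ half-ties)
  u_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(r$u_statistic, u_oracle)
  expect_equal(r$u_statistic,
               unname(suppressWarnings(wilcox.test(a, b)$statistic)))

  same <- ranksum_and_effect(a, a)
  expect_equal(same$cohens_d, 0)
  expect_gte(same$p_value, 0.99)

  withr::with_seed(13, {
    x <- rnorm(200); y <- rnorm(200, 1)
    d <- ranksum_and_effect(y, x)$cohens_d
    expect_gte(d, 0.7); expect_lte(d, 1.3)
  })
})
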