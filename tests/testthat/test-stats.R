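# two-point sample with exact mean m and sample SD s of the differences
pair_with <- function(m, s) {
  paired_sample(c(0, 0), c(m - s / sqrt(2), m + s / sqrt(2)))
}

test_that("Bland-Altman arithmetic: CRP = 1.96 SD, LoA = mean -/+ CRP", {
  ba <- bland_altman(pair_with(-5.27, 8.99))
  expect_equal(ba$mean_diff, -5.27, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 8.99, tolerance = 1e-12)
  expect_equal(ba$crp, 1.96 * 8.99, tolerance = 1e-12)
  expect_equal(ba$loa_lower, -5.27 - 1.96 * 8.99)
  expect_equal(ba$loa_upper, -5.27 + 1.96 * 8.99)
  # identical arms
  same <- bland_altman(paired_sample(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$crp, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))
})

test_that("LoA always bracket the mean difference with width 2 CRP", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    ba <- bland_altman(paired_sample(rnorm(n), rnorm(n, sd = runif(1, 0.1, 5))))
    expect_lte(ba$loa_lower, ba$mean_diff)
    expect_gte(ba$loa_upper, ba$mean_diff)
    expect_equal(ba$loa_upper - ba$loa_lower, 2 * ba$crp)
    expect_gte(ba$crp, 0)
  }
})

test_that("tidy/glance/autoplot methods work on agreement results", {
  ba <- bland_altman(paired_sample(c(1, 2, 4), c(2, 2, 5)))
  td <- tidy(ba)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("mean_diff", "sd_diff", "crp", "loa_lower", "loa_upper",
                     "n"))
  expect_equal(glance(ba), td)
  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("Pearson correlation matches the product-moment formula", {
  expect_equal(pearson_r(paired_sample(1:5, 2 * (1:5) + 1)), 1)
  expect_equal(pearson_r(paired_sample(1:5, -(1:5))), -1)
  x <- c(1.2, 3.4, 2.2, 5.0); y <- c(0.7, 2.9, 3.1, 4.2)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(paired_sample(x, y)), oracle, tolerance = 1e-12)
  # invariance under positive affine maps
  expect_equal(pearson_r(paired_sample(3 * x + 2, 0.5 * y - 1)),
               pearson_r(paired_sample(x, y)), tolerance = 1e-12)
  expect_error(pearson_r(paired_sample(c(1, 1, 1), y[1:3])), "zero variance")
})

test_that("paired t-test matches its formula, an integration oracle and
           stats::t.test", {
  x <- c(12.1, 14.2, 11.8, 13.0, 12.5)
  y <- c(13.0, 14.8, 12.2, 13.9, 12.4)
  res <- paired_t_test(paired_sample(x, y))
  d <- y - x
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  # numerical integration of the t density as an independent p-value oracle
  p_oracle <- 2 * stats::integrate(function(t) stats::dt(t, df = 4),
                                   abs(res$statistic), Inf)$value
  expect_equal(res$p_value, p_oracle, tolerance = 1e-6)
  tt <- stats::t.test(y, x, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # symmetric differences with exact zero mean
  sym <- paired_t_test(paired_sample(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  # t is invariant under positive scaling of the differences
  res2 <- paired_t_test(paired_sample(2 * x, 2 * y))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  expect_error(paired_t_test(paired_sample(x, x)), "degenerate")
})

test_that("Cohen's kappa matches the marginal formula and e1071", {
  # perfect agreement
  expect_equal(cohens_kappa(c("a", "b", "a", "b"), c("a", "b", "a", "b"))$kappa,
               1)
  # 2x2 table {aa = 20, ab = 5, ba = 10, bb = 15}: kappa = 0.4 by hand
  ra <- c(rep("x", 20), rep("x", 5), rep("y", 10), rep("y", 15))
  rb <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  res <- cohens_kappa(ra, rb)
  expect_equal(res$observed_agreement, 0.7)
  expect_equal(res$expected_agreement, 0.5)
  expect_equal(res$kappa, 0.4, tolerance = 1e-12)
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(res$kappa,
                 e1071::classAgreement(table(ra, rb))$kappa, tolerance = 1e-12)
  }
  # observed agreement at exactly the chance level -> kappa = 0
  ra0 <- c("x", "x", "y", "y")
  rb0 <- c("x", "y", "x", "y")
  expect_equal(cohens_kappa(ra0, rb0)$kappa, 0)
  expect_error(cohens_kappa(c("x", "x"), c("x", "x")), "undefined")
  expect_error(cohens_kappa(c("x"), c("x", "y")), "equal length")
})

test_that("kappa stays in [-1, 1] for random ratings", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    k <- sample(2:4, 1)
    ra <- sample(letters[1:k], n, replace = TRUE)
    rb <- sample(letters[1:k], n, replace = TRUE)
    res <- tryCatch(cohens_kappa(ra, rb), error = function(e) NULL)
    if (!is.null(res)) {
      expect_gte(res$kappa, -1)
      expect_lte(res$kappa, 1)
    }
  }
})

test_that("median and quartile deviation use linear interpolation", {
  s <- summarize_median_qd(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$qd, 1.0)
  expect_equal(summarize_median_qd(rep(7, 4))$qd, 0)
  one <- summarize_median_qd(4.2)
  expect_equal(one$median, 4.2)
  expect_equal(one$qd, 0)
})

test_that("paired samples validate their inputs", {
  expect_error(paired_sample(1:3, 1:4), "equal length")
  expect_error(paired_sample(1, 2), "at least 2")
  expect_error(paired_sample(c(1, NA), c(1, 2)), "finite")
})
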