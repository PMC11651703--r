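test_that("pooled bootstrap separates grossly different groups", {
  set.seed(1)
  g1 <- rnorm(20, 0); g2 <- rnorm(20, 5)
  bt <- bootstrap_group_test(list(g1, g2), "t", n_iter = 2000, seed = 3)
  expect_lt(bt$p, 0.01)
  bf <- bootstrap_group_test(list(g1, g2, rnorm(15, 2)), "F",
                             n_iter = 2000, seed = 4)
  expect_lt(bf$p, 0.01)
  # identical data: degenerate, p = 1 with warning
  expect_warning(b0 <- bootstrap_group_test(list(rep(1, 5), rep(1, 6)), "t",
                                            n_iter = 100, seed = 1),
                 "identical")
  expect_equal(b0$p, 1)
  expect_error(bootstrap_group_test(list(rnorm(5)), "t"), "two")
})

test_that("bootstrap results are reproducible given a seed", {
  x <- rnorm(25); y <- rnorm(25)
  a <- bootstrap_association(x, y, "pearson", n_iter = 500, seed = 7)
  b <- bootstrap_association(x, y, "pearson", n_iter = 500, seed = 7)
  expect_identical(a$null, b$null)
  expect_identical(a$p, b$p)
})

test_that("two-tailed p is symmetric under sign flip of the statistic", {
  set.seed(2)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  a <- bootstrap_association(x, y, "pearson", n_iter = 2000, seed = 5)
  b <- bootstrap_association(x, -y, "pearson", n_iter = 2000, seed = 5)
  expect_equal(a$p, b$p)
  expect_equal(a$observed, -b$observed)
})

test_that("regression slope bootstrap matches the OLS slope", {
  set.seed(3)
  x <- rnorm(40); y <- 2 + 1.5 * x + rnorm(40)
  bt <- bootstrap_association(x, y, "regression_beta", n_iter = 1000, seed = 1)
  expect_equal(bt$observed, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  expect_lt(bt$p, 0.05)
})

test_that("bootstrapped chi-squared detects association and respects the null", {
  assoc <- matrix(c(30, 5, 5, 30), 2)
  expect_lt(bootstrap_chi2(assoc, n_iter = 2000, seed = 2)$p, 0.01)
  flat <- matrix(c(20, 20, 21, 19), 2)
  expect_gt(bootstrap_chi2(flat, n_iter = 2000, seed = 2)$p, 0.2)
  expect_equal(bootstrap_chi2(assoc, 200, seed = 9)$observed,
               unname(suppressWarnings(
                 chisq.test(assoc, correct = FALSE)$statistic)),
               tolerance = 1e-10)
})

test_that("skipped correlation resists a gross bivariate outlier", {
  x <- seq(1, 20); y <- 2 * x + 1          # perfectly collinear
  rc0 <- robust_correlation(x, y, n_iter = 500, seed = 1)
  expect_equal(rc0$r, 1, tolerance = 1e-12)
  expect_equal(rc0$n_outliers, 0)
  xo <- c(x, 30); yo <- c(y, -40)          # one wild point
  rc <- robust_correlation(xo, yo, n_iter = 500, seed = 1)
  expect_gt(rc$n_outliers, 0)
  expect_equal(rc$r, 1, tolerance = 1e-6)  # restored after skipping
  expect_lt(rc$r_pearson, 0.9)             # plain Pearson is dragged down
})

test_that("skipped correlation is unbiased under independence", {
  set.seed(11)
  rs <- replicate(300, {
    x <- rnorm(44); y <- rnorm(44)
    out <- skipped <- riskconform:::skipped_outliers(x, y)
    cor(x[!out], y[!out])
  })
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("JZS Bayes factor favors the null for similar groups only", {
  set.seed(4)
  same <- list(rnorm(60), rnorm(60))
  expect_gt(bayes_factor_null("ttest", same), 1)
  apart <- list(rnorm(20), rnorm(20, 2))
  expect_lt(bayes_factor_null("ttest", apart), 1)
  # correlation flavor, direction checks
  x <- rnorm(50); expect_gt(bayes_factor_null("correlation", list(x, rnorm(50))), 1)
  y <- x + rnorm(50, sd = 0.3)
  expect_lt(bayes_factor_null("correlation", list(x, y)), 1)
})

test_that("JZS t Bayes factor matches a Monte-Carlo prior-integration oracle", {
  set.seed(5)
  x <- rnorm(20, 0.2); y <- rnorm(20)
  bf <- bayes_factor_null("ttest", list(x, y))
  # oracle: average the alternative's marginal over draws of g from its
  # inverse-gamma prior instead of quadrature
  n1 <- 20; n2 <- 20; df <- n1 + n2 - 2; neff <- n1 * n2 / (n1 + n2)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df)
  t <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
  g <- 1 / rgamma(2e6, shape = 0.5, rate = (sqrt(2) / 2)^2 / 2)
  alt <- mean((1 + neff * g)^(-0.5) * (1 + t^2 / ((1 + neff * g) * df))^(-(df + 1) / 2))
  null <- (1 + t^2 / df)^(-(df + 1) / 2)
  expect_equal(bf, null / alt, tolerance = 0.02)
})

test_that("residualization matches the normal-equations solution", {
  y <- c(3.1, 4.0, 5.2, 6.1, 7.3)
  x <- c(1, 2, 3, 4, 5)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)      # closed-form OLS oracle
  expect_equal(residualize(y, x), as.numeric(y - X %*% beta), tolerance = 1e-10)
  # orthogonal covariate leaves only the mean removed
  yo <- c(1, -1, 1, -1); xo <- c(1, 1, -1, -1)
  expect_equal(residualize(yo, xo), yo - mean(yo), tolerance = 1e-10)
  # exact linear dependence gives ~zero residuals
  expect_equal(residualize(2 * x + 1, x), rep(0, 5), tolerance = 1e-10)
  expect_error(residualize(y, cbind(x, 2 * x)), "rank")
})
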