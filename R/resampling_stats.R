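new_bootstrap_result <- function(observed, null, kind, n_iter, seed) {
  # ties at the boundary count toward the null (conservative two-tailed rule)
  p <- mean(abs(null) >= abs(observed))
  p <- max(p, 0)
  structure(list(observed = observed, null = null, p = p,
                 n_iter = n_iter, seed = seed, kind = kind),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: statistic = %.4g, p = %.4g (%d iterations)\n",
              x$kind, x$observed, x$p, x$n_iter))
  invisible(x)
}

stat_t <- function(values, grp_sizes) {
  idx <- rep(seq_along(grp_sizes), grp_sizes)
  x <- values[idx == 1]; y <- values[idx == 2]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
}

stat_F <- function(values, grp_sizes) {
  g <- factor(rep(seq_along(grp_sizes), grp_sizes))
  gm <- tapply(values, g, mean)
  ssb <- sum(grp_sizes * (gm - mean(values))^2)
  ssw <- sum((values - gm[g])^2)
  dfb <- length(grp_sizes) - 1
  dfw <- length(values) - length(grp_sizes)
  (ssb / dfb) / (ssw / dfw)
}

#' Pooled-bootstrap group comparison
#'
#' Nonparametric null for a two-group t statistic or k-group one-way
#' F statistic: all values are pooled, then resampled with replacement into
#' groups of the original sizes; the statistic recomputed on each resample
#' forms the null distribution.  The two-tailed p value is the fraction of
#' null statistics whose absolute value is at least that of the observed
#' statistic (so statistics beating 9,500 of 10,000 null draws are
#' significant at alpha = 0.05).
#'
#' @param values_by_group List of numeric vectors, one per group.
#' @param statistic `"t"` (2 groups) or `"F"` (>= 2 groups).
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Optional integer seed.
#' @return A `bootstrap_result` (observed statistic, null draws, p).
#' @examples
#' bootstrap_group_test(list(rnorm(20), rnorm(20, 1)), "t",
#'                      n_iter = 1000, seed = 1)
#' @export
bootstrap_group_test <- function(values_by_group, statistic = c("t", "F"),
                                 n_iter = 10000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(values_by_group) < 2 || any(!lengths(values_by_group)))
    stop("need at least two nonempty groups", call. = FALSE)
  if (statistic == "t" && length(values_by_group) != 2)
    stop("t statistic requires exactly two groups", call. = FALSE)
  sizes <- lengths(values_by_group)
  pooled <- unlist(values_by_group, use.names = FALSE)
  fun <- if (statistic == "t") stat_t else stat_F
  obs <- fun(pooled, sizes)
  if (var(pooled) < .Machine$double.eps) {
    warning("all values identical; p = 1", call. = FALSE)
    return(new_bootstrap_result(0, rep(0, n_iter), paste0("group_", statistic),
                                n_iter, seed))
  }
  with_seed(seed, {
    n <- sum(sizes)
    null <- vapply(seq_len(n_iter), function(i) {
      fun(sample(pooled, n, replace = TRUE), sizes)
    }, numeric(1))
    new_bootstrap_result(obs, null, paste0("group_", statistic), n_iter, seed)
  })
}

#' Pooled-bootstrap association test
#'
#' Null for a correlation or simple-regression slope built by "unpairing"
#' the variables: each iteration independently resamples `x` and `y` with
#' replacement, destroying any pairing while keeping the marginals.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @param statistic `"pearson"` (correlation) or `"regression_beta"`
#'   (OLS slope of y on x).
#' @inheritParams bootstrap_group_test
#' @return A `bootstrap_result`.
#' @export
bootstrap_association <- function(x, y, statistic = c("pearson", "regression_beta"),
                                  n_iter = 10000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must be paired vectors of length >= 3", call. = FALSE)
  fun <- if (statistic == "pearson") function(a, b) cor(a, b)
         else function(a, b) cov(a, b) / var(a)
  obs <- fun(x, y)
  with_seed(seed, {
    n <- length(x)
    null <- vapply(seq_len(n_iter), function(i) {
      fun(sample(x, n, replace = TRUE), sample(y, n, replace = TRUE))
    }, numeric(1))
    null[!is.finite(null)] <- 0
    new_bootstrap_result(obs, null, paste0("association_", statistic),
                         n_iter, seed)
  })
}

chi2_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Bootstrapped chi-squared test on a two-way count table
#'
#' Null built by resampling category labels from the pooled margin and
#' reassigning them to groups of the original sizes, then recomputing the
#' chi-squared statistic.
#'
#' @param table Two-way contingency table (groups x categories).
#' @inheritParams bootstrap_group_test
#' @return A `bootstrap_result`.
#' @export
bootstrap_chi2 <- function(table, n_iter = 10000, seed = NULL) {
  tab <- as.matrix(table)
  if (length(dim(tab)) != 2 || any(tab < 0))
    stop("table must be a two-way count table", call. = FALSE)
  obs <- chi2_stat(tab)
  sizes <- rowSums(tab)
  pooled <- rep(seq_len(ncol(tab)), colSums(tab))
  with_seed(seed, {
    null <- vapply(seq_len(n_iter), function(i) {
      lab <- sample(pooled, sum(sizes), replace = TRUE)
      g <- rep(seq_along(sizes), sizes)
      t2 <- table(factor(g, seq_along(sizes)), factor(lab, seq_len(ncol(tab))))
      chi2_stat(as.matrix(t2))
    }, numeric(1))
    null[!is.finite(null)] <- 0
    new_bootstrap_result(obs, null, "chi2", n_iter, seed)
  })
}

# projection-based bivariate outlier flags (boxplot rule on every
# projection through the coordinatewise-median center)
skipped_outliers <- function(x, y) {
  X <- cbind(x, y)
  ctr <- apply(X, 2, median)
  Xc <- sweep(X, 2, ctr)
  n <- nrow(X)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d <- Xc[i, ]
    nrm2 <- sum(d^2)
    if (nrm2 < .Machine$double.eps) next
    z <- as.numeric(Xc %*% d) / sqrt(nrm2)
    q <- quantile(z, c(0.25, 0.75), names = FALSE, type = 6)
    iqr <- q[2] - q[1]
    flagged <- flagged | (z < q[1] - 1.5 * iqr | z > q[2] + 1.5 * iqr)
  }
  flagged
}

#' Robust (skipped) correlation
#'
#' Skipped Pearson correlation: bivariate outliers are flagged by
#' projecting the points onto every direction through the
#' coordinatewise-median center and applying the boxplot rule to each
#' projection; the Pearson correlation is then computed on the retained
#' points, with a pooled-bootstrap ("unpairing") p value.  The plain
#' Pearson value on all points is reported alongside.
#'
#' @param x,y Numeric vectors (length >= 4).
#' @param n_iter Bootstrap iterations for the p value.
#' @param seed Optional integer seed.
#' @return List: `r` (skipped), `p`, `r_pearson` (unskipped), `n_outliers`,
#'   `outliers` (logical), `boot` (the `bootstrap_result`).
#' @export
robust_correlation <- function(x, y, n_iter = 10000, seed = NULL) {
  if (length(x) != length(y) || length(x) < 4)
    stop("need paired vectors of length >= 4", call. = FALSE)
  out <- skipped_outliers(x, y)
  if (sum(!out) < 4) out <- rep(FALSE, length(x))
  xr <- x[!out]; yr <- y[!out]
  boot <- bootstrap_association(xr, yr, "pearson", n_iter = n_iter, seed = seed)
  list(r = cor(xr, yr), p = boot$p, r_pearson = cor(x, y),
       n_outliers = sum(out), outliers = out, boot = boot)
}

# JZS (Zellner-Siow) Bayes factors with the conventional default scale
jzs_bf10_t <- function(t, n_eff, df, rscale = sqrt(2) / 2) {
  marg_alt <- integrate(function(g) {
    exp((-(df + 1) / 2) * log1p(t^2 / ((1 + n_eff * g) * df)) -
          0.5 * log1p(n_eff * g) +
          dgamma(1 / g, shape = 0.5, rate = rscale^2 / 2, log = TRUE) -
          2 * log(g))
  }, 0, Inf, rel.tol = 1e-9)$value
  marg_null <- (1 + t^2 / df)^(-(df + 1) / 2)
  marg_alt / marg_null
}

#' Default-prior Bayes factor in favor of the null
#'
#' JZS (Jeffreys--Zellner--Siow) Bayes factor with the conventional
#' Cauchy(0, sqrt(2)/2) effect-size prior, reported as `BF_null`
#' (evidence for the null; values > 1 favor no difference / no
#' association).  For `kind = "ttest"` supply two groups in `data` (list of
#' two vectors) or a single vector (one-sample against 0); for
#' `kind = "correlation"` supply `data = list(x, y)` -- the correlation is
#' assessed through the equivalent single-predictor regression t statistic.
#'
#' @param kind `"ttest"` or `"correlation"`.
#' @param data List of numeric vectors as described.
#' @return Scalar `BF_null`.
#' @export
bayes_factor_null <- function(kind = c("ttest", "correlation"), data) {
  kind <- match.arg(kind)
  if (kind == "ttest") {
    if (is.list(data) && length(data) == 2) {
      x <- data[[1]]; y <- data[[2]]
      n1 <- length(x); n2 <- length(y)
      t <- stat_t(c(x, y), c(n1, n2))
      bf10 <- jzs_bf10_t(t, n_eff = n1 * n2 / (n1 + n2), df = n1 + n2 - 2)
    } else {
      x <- if (is.list(data)) data[[1]] else data
      t <- mean(x) / (sd(x) / sqrt(length(x)))
      bf10 <- jzs_bf10_t(t, n_eff = length(x), df = length(x) - 1)
    }
  } else {
    x <- data[[1]]; y <- data[[2]]
    n <- length(x)
    if (n < 4) stop("correlation BF needs n >= 4", call. = FALSE)
    r <- cor(x, y)
    t <- r * sqrt((n - 2) / (1 - r^2))
    bf10 <- jzs_bf10_t(t, n_eff = n, df = n - 2)
  }
  1 / bf10
}

#' Regress covariates out of a response
#'
#' Ordinary least-squares residuals of `y` on an intercept plus the given
#' covariates; downstream group comparisons or correlations are then run on
#' the residuals (the covariate-control procedure for age, cognitive score,
#' or risk preference).
#'
#' @param y Numeric response.
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @return Residual vector (same length as `y`).
#' @export
residualize <- function(y, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient", call. = FALSE)
  as.numeric(y - X %*% qr.solve(X, y))
}
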