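#' Prior configuration for hierarchical estimation
#'
#' Group-level means get `Normal(0, 10)` priors and group-level SDs
#' `half-Cauchy(0, 2.5)`; inverse temperature and risk preference are
#' estimated on the log scale and exponentiated (so their population
#' distributions are log-normal) while OCU stays on the natural scale.
#' Mixture weights are not hierarchical: each subject's simplex gets a flat
#' (uniform-on-simplex) prior.  Optional hard upper bounds on beta and alpha
#' truncate the individual-level distributions (used in some sensitivity
#' fits, e.g. beta <= 50, alpha <= 2).
#'
#' @param mu_sd SD of the normal prior on group means (default 10).
#' @param sigma_scale Scale of the half-Cauchy prior on group SDs (2.5).
#' @param beta_max,alpha_max Optional upper bounds on the natural scale.
#' @param diff_sd SD of the normal prior on group-difference offsets (10).
#' @return A `prior_config` list.
#' @export
prior_config <- function(mu_sd = 10, sigma_scale = 2.5,
                         beta_max = NULL, alpha_max = NULL, diff_sd = 10) {
  structure(list(mu_sd = mu_sd, sigma_scale = sigma_scale,
                 beta_max = beta_max, alpha_max = alpha_max, diff_sd = diff_sd),
            class = "prior_config")
}

#' MCMC configuration
#'
#' Defaults mirror the full estimation protocol: 4 chains of 5000 draws
#' each, the first 2000 discarded as burn-in, leaving 12000 post-burn-in
#' draws.  Reduced settings (e.g. `n_draws = 1500`, `n_burnin = 500`) are
#' appropriate for recovery studies and tests.
#'
#' @param n_chains Number of chains.
#' @param n_draws Draws per chain (including burn-in).
#' @param n_burnin Burn-in draws discarded per chain.
#' @param n_adapt Sampler adaptation iterations before burn-in.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_draws = 5000, n_burnin = 2000,
                        n_adapt = 500, seed = 1) {
  if (n_burnin >= n_draws) stop("n_burnin must be < n_draws", call. = FALSE)
  structure(list(n_chains = n_chains, n_draws = n_draws, n_burnin = n_burnin,
                 n_adapt = n_adapt, seed = as.integer(seed),
                 n_kept = n_chains * (n_draws - n_burnin)),
            class = "mcmc_config")
}

# ---- JAGS model construction -------------------------------------------------

jags_model_string <- function(spec, priors, has_groups) {
  has_ocu <- "ocu" %in% spec$hier_params
  mu_tau <- 1 / priors$mu_sd^2
  sig_tau <- 1 / priors$sigma_scale^2
  diff_tau <- 1 / priors$diff_sd^2
  b_bound <- if (!is.null(priors$beta_max))
    sprintf(" T(, %.10g)", log(priors$beta_max)) else ""
  a_bound <- if (!is.null(priors$alpha_max))
    sprintf(" T(, %.10g)", log(priors$alpha_max)) else ""

  du <- "
    du[t] <- ph[t]*pow(vhs[t], alpha[sub[t]]) + (1-ph[t])*pow(vls[t], alpha[sub[t]])
           - ph[t]*pow(vhr[t], alpha[sub[t]]) - (1-ph[t])*pow(vlr[t], alpha[sub[t]])"
  lik <- switch(spec$name,
    solo_rp = "
    p[t] <- ilogit(beta[sub[t]] * du[t])",
    ocu = "
    p[t] <- ilogit(beta[sub[t]] * (du[t] + delta[t] * ocu[sub[t]]))",
    ocu_free = "
    psolo[t] <- ilogit(beta[sub[t]] * du[t])
    p[t] <- fs[t] * wf[sub[t]] + fr[t] * (1 - wf[sub[t]]) +
            (1 - fs[t] - fr[t]) * psolo[t]",
    hybrid = "
    pocu[t] <- ilogit(beta[sub[t]] * (du[t] + delta[t] * ocu[sub[t]]))
    p[t] <- fs[t] * (w[sub[t],1] + w[sub[t],3] * pocu[t]) +
            fr[t] * (w[sub[t],2] + w[sub[t],3] * pocu[t]) +
            (1 - fs[t] - fr[t]) * pocu[t]")

  subj <- paste0("
    lb[i] ~ dnorm(mu_b + d_b[g[i]], tau_b)", b_bound, "
    beta[i] <- exp(lb[i])
    la[i] ~ dnorm(mu_a, tau_a)", a_bound, "
    alpha[i] <- exp(la[i])",
    if (has_ocu) "
    ocu[i] ~ dnorm(mu_o, tau_o)" else "",
    switch(spec$name,
      hybrid = "
    w[i, 1:3] ~ ddirch(a_w)",
      ocu_free = "
    wf[i] ~ dunif(0, 1)",
      ""))

  gdiff <- if (has_groups) paste0("
  d_b[1] <- 0
  for (gg in 2:G) { d_b[gg] ~ dnorm(0, ", sprintf("%.10g", diff_tau), ") }") else "
  d_b[1] <- 0"

  hyper <- paste0("
  mu_b ~ dnorm(0, ", sprintf("%.10g", mu_tau), ")
  sig_b ~ dt(0, ", sprintf("%.10g", sig_tau), ", 1) T(0,)
  tau_b <- pow(sig_b, -2)
  mu_a ~ dnorm(0, ", sprintf("%.10g", mu_tau), ")
  sig_a ~ dt(0, ", sprintf("%.10g", sig_tau), ", 1) T(0,)
  tau_a <- pow(sig_a, -2)",
  if (has_ocu) paste0("
  mu_o ~ dnorm(0, ", sprintf("%.10g", mu_tau), ")
  sig_o ~ dt(0, ", sprintf("%.10g", sig_tau), ", 1) T(0,)
  tau_o <- pow(sig_o, -2)") else "")

  paste0("model {
  for (t in 1:N) {", du, lik, "
    pc[t] <- max(1.0E-9, min(1 - 1.0E-9, p[t]))
    y[t] ~ dbern(pc[t])
  }
  for (i in 1:S) {", subj, "
  }", gdiff, hyper, "
}")
}

jags_monitors <- function(spec, has_groups) {
  m <- c("lb", "la", "mu_b", "sig_b", "mu_a", "sig_a")
  if ("ocu" %in% spec$hier_params) m <- c(m, "ocu", "mu_o", "sig_o")
  if (spec$name == "hybrid") m <- c(m, "w")
  if (spec$name == "ocu_free") m <- c(m, "wf")
  if (has_groups) m <- c(m, "d_b")
  m
}

# split-half R-hat (potential scale reduction) on an iterations x chains matrix
split_rhat <- function(x) {
  n <- floor(nrow(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  v <- apply(halves, 2, var)
  W <- mean(v)
  B <- n * var(mu)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a choice model hierarchically by MCMC
#'
#' Estimates the given model for all subjects jointly: individual parameters
#' are drawn from common group-level normal distributions (log scale for
#' beta and alpha), with flat-simplex individual weights, using JAGS
#' (Gibbs/slice sampling).  When `group_map` assigns subjects to more than
#' one group, an additive group-difference offset on the log-beta group
#' mean is estimated for every non-reference group (reference = first
#' level, normally `NC`), so lesion-like shifts in inverse temperature can
#' be read directly off the posterior.
#'
#' @param model Model name or [model_spec()].
#' @param dataset Choice dataset ([simulate_choices()] schema with `choice`).
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param group_map Optional named vector `subject_id -> group label`;
#'   defaults to the dataset's `group` column if present, else one group.
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return An `hb_fit` object: per-subject posterior-median parameters
#'   (`$subjects`, weights renormalized to the simplex with the
#'   pre-normalization deficit recorded), hyperparameter summaries
#'   (`$hyper`), group-difference draws (`$group_diff`), R-hat per monitored
#'   scalar (`$rhat`), convergence flag, per-subject negative log likelihood
#'   at the medians, and the kept posterior draws (`$draws`, a
#'   `coda::mcmc.list`).  Non-convergence (any R-hat >= 1.1) sets
#'   `converged = FALSE` and raises a warning, never a silent success.
#' @export
fit_hierarchical <- function(model, dataset, priors = prior_config(),
                             mcmc = mcmc_config(), group_map = NULL,
                             quiet = TRUE) {
  spec <- as_model_spec(model)
  ids <- unique(dataset$subject_id)
  S <- length(ids)
  sub <- match(dataset$subject_id, ids)

  if (is.null(group_map) && "group" %in% names(dataset))
    group_map <- tapply(as.character(dataset$group), dataset$subject_id, `[`, 1)
  groups <- if (is.null(group_map)) rep("ALL", S) else as.character(group_map[ids])
  glev <- intersect(c(GROUP_LABELS, "ALL", sort(unique(groups))), unique(groups))
  g <- match(groups, glev)
  has_groups <- length(glev) > 1

  dat <- list(
    N = nrow(dataset), S = S, y = dataset$choice, sub = sub,
    ph = dataset$p_high, vhs = dataset$v_high_safe, vls = dataset$v_low_safe,
    vhr = dataset$v_high_risky, vlr = dataset$v_low_risky,
    g = g, G = max(2L, length(glev)))
  if (spec$name %in% c("ocu", "hybrid")) dat$delta <- dataset$delta
  if (spec$name %in% c("ocu_free", "hybrid")) {
    dat$fs <- as.numeric(dataset$trial_type == "INFO_SAFE")
    dat$fr <- as.numeric(dataset$trial_type == "INFO_RISKY")
  }
  if (spec$name == "hybrid") dat$a_w <- c(1, 1, 1)
  if (!has_groups) { dat$g <- rep(1L, S); dat$G <- 2L }
  # G >= 2 keeps the d_b loop syntactically valid; unused offsets just
  # sample their prior when no subject maps to them.

  inits <- lapply(seq_len(mcmc$n_chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed + c,
         mu_b = 0.5, mu_a = -0.2, sig_b = 0.5, sig_a = 0.3)
  })

  mstr <- jags_model_string(spec, priors, has_groups)
  jm <- rjags::jags.model(textConnection(mstr), data = dat,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = quiet)
  if (mcmc$n_burnin > 0)
    update(jm, mcmc$n_burnin, progress.bar = if (quiet) "none" else "text")
  draws <- rjags::coda.samples(jm, jags_monitors(spec, has_groups),
                               n.iter = mcmc$n_draws - mcmc$n_burnin,
                               progress.bar = if (quiet) "none" else "text")

  mat <- do.call(rbind, lapply(draws, as.matrix))
  vn <- colnames(mat)

  # R-hat over every monitored scalar that actually varies
  arr <- array(unlist(lapply(draws, as.matrix)),
               dim = c(nrow(draws[[1]]), length(vn), length(draws)))
  rhat <- vapply(seq_along(vn), function(j) split_rhat(arr[, j, ]), numeric(1))
  names(rhat) <- vn
  rhat <- rhat[!is.na(rhat)]
  converged <- all(rhat < 1.1)
  if (!converged)
    warning("fit_hierarchical: ", sum(rhat >= 1.1),
            " parameters with R-hat >= 1.1; treat estimates with caution",
            call. = FALSE)

  med <- apply(mat, 2, median)
  col <- function(stub, i) med[[sprintf("%s[%d]", stub, i)]]
  subjects <- data.frame(subject_id = ids, group = groups,
                         beta = exp(vapply(seq_len(S), function(i) col("lb", i), 1)),
                         alpha = exp(vapply(seq_len(S), function(i) col("la", i), 1)))
  subjects$ocu <- if ("ocu" %in% spec$hier_params)
    vapply(seq_len(S), function(i) col("ocu", i), 1) else 0
  if (spec$name == "hybrid") {
    wm <- cbind(vapply(seq_len(S), function(i) med[[sprintf("w[%d,1]", i)]], 1),
                vapply(seq_len(S), function(i) med[[sprintf("w[%d,2]", i)]], 1),
                vapply(seq_len(S), function(i) med[[sprintf("w[%d,3]", i)]], 1))
    tot <- rowSums(wm)
    subjects$w_follow <- wm[, 1] / tot
    subjects$w_oppose <- wm[, 2] / tot
    subjects$w_utility <- wm[, 3] / tot
    subjects$w_median_deficit <- 1 - tot
  } else if (spec$name == "ocu_free") {
    wf <- vapply(seq_len(S), function(i) col("wf", i), 1)
    subjects$w_follow <- wf; subjects$w_oppose <- 1 - wf; subjects$w_utility <- 0
  } else {
    subjects$w_follow <- 0; subjects$w_oppose <- 0; subjects$w_utility <- 1
  }

  subjects$neg_ll <- vapply(seq_len(S), function(i) {
    d <- dataset[sub == i, , drop = FALSE]
    neg_log_likelihood(spec, d, d$choice, agent_row_params(subjects, i))
  }, numeric(1))

  hyper_names <- intersect(c("mu_b", "sig_b", "mu_a", "sig_a", "mu_o", "sig_o"), vn)
  hyper <- data.frame(param = hyper_names,
                      median = med[hyper_names],
                      mean = colMeans(mat[, hyper_names, drop = FALSE]),
                      q2.5 = apply(mat[, hyper_names, drop = FALSE], 2, quantile, 0.025),
                      q97.5 = apply(mat[, hyper_names, drop = FALSE], 2, quantile, 0.975),
                      row.names = NULL)

  group_diff <- NULL
  if (has_groups && length(glev) > 1) {
    group_diff <- lapply(seq_along(glev)[-1], function(k) mat[, sprintf("d_b[%d]", k)])
    names(group_diff) <- paste0("d_logbeta_", glev[-1])
  }

  structure(list(model = spec, subjects = subjects, hyper = hyper,
                 group_diff = group_diff, group_levels = glev,
                 rhat = rhat, converged = converged,
                 n_divergent = NA_integer_,  # divergence counts are HMC-specific
                 draws = draws, mcmc = mcmc, priors = priors,
                 subject_ids = ids),
            class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("<hb_fit>", x$model$name, "model,", nrow(x$subjects), "subjects,",
      x$mcmc$n_kept, "post-burn-in draws\n")
  cat("  max R-hat:", sprintf("%.3f", max(x$rhat)),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$group_diff))
    for (nm in names(x$group_diff)) {
      ci <- quantile(x$group_diff[[nm]], c(0.025, 0.975))
      cat(sprintf("  %s: mean %.3f, 95%% CI [%.3f, %.3f]\n",
                  nm, mean(x$group_diff[[nm]]), ci[1], ci[2]))
    }
  invisible(x)
}

#' Posterior-median parameters per subject
#'
#' Elementwise posterior medians on the natural scale; simplex weights are
#' renormalized after taking componentwise medians (the per-subject
#' pre-normalization deficit is kept in the fit's `subjects` table).
#'
#' @param fit An `hb_fit`.
#' @return Data frame, one row per subject, columns `subject_id`, `group`,
#'   `beta`, `alpha`, `ocu`, `w_follow`, `w_oppose`, `w_utility`, `neg_ll`.
#' @export
median_params <- function(fit) {
  stopifnot(inherits(fit, "hb_fit"))
  fit$subjects
}

#' Solo-trial utility-model fit metric
#'
#' Per-subject negative log likelihood on Solo trials at the
#' posterior-median parameters of a solo risk-preference fit.  Larger values
#' mean worse utility-based fit; this is the "disruption" index whose group
#' differences and correlation with the follow weight are the headline
#' behavioral comparisons.
#'
#' @param fit An `hb_fit` of the `solo_rp` model.
#' @param dataset The dataset the fit used.
#' @return Data frame `subject_id`, `group`, `neg_ll_solo`.
#' @export
solo_fit_metric <- function(fit, dataset) {
  stopifnot(inherits(fit, "hb_fit"))
  med <- median_params(fit)
  nll <- vapply(seq_len(nrow(med)), function(i) {
    d <- dataset[dataset$subject_id == med$subject_id[i], , drop = FALSE]
    neg_log_likelihood("solo_rp", d, d$choice, agent_row_params(med, i),
                       trial_filter = "SOLO")
  }, numeric(1))
  data.frame(subject_id = med$subject_id, group = med$group, neg_ll_solo = nll)
}

#' Credible-interval test on a group-difference parameter
#'
#' Central 95% credible interval of the posterior draws of a
#' group-difference offset; the difference is called credible when the
#' interval excludes zero.
#'
#' @param fit An `hb_fit` estimated with group labels.
#' @param param Name of the offset, e.g. `"d_logbeta_INSULA"` (default: all).
#' @param level Credible level (default 0.95).
#' @return Data frame with posterior mean, interval bounds and a
#'   `crosses_zero` flag per parameter.
#' @export
group_difference_test <- function(fit, param = NULL, level = 0.95) {
  stopifnot(inherits(fit, "hb_fit"))
  if (is.null(fit$group_diff))
    stop("fit has no group-difference parameters", call. = FALSE)
  params <- if (is.null(param)) names(fit$group_diff) else param
  a <- (1 - level) / 2
  out <- lapply(params, function(nm) {
    d <- fit$group_diff[[nm]]
    if (is.null(d)) stop("no draws for ", nm, call. = FALSE)
    ci <- unname(quantile(d, c(a, 1 - a)))
    data.frame(param = nm, mean = mean(d), lower = ci[1], upper = ci[2],
               crosses_zero = ci[1] <= 0 && ci[2] >= 0)
  })
  do.call(rbind, out)
}

#' Maximum-likelihood fit of one subject (reference fitter)
#'
#' Direct per-subject maximum-likelihood estimation by coarse grid search
#' followed by local refinement with `optim`.  Serves as an independent
#' check on the hierarchical machinery and as a fallback for single
#' subjects; headline analyses use [fit_hierarchical()].
#'
#' @param model Model name or spec.
#' @param trials Trial table for one subject.
#' @param choices 0/1 choice vector.
#' @return List with `params` ([agent_parameters()]) and `neg_ll`.
#' @export
fit_ml_subject <- function(model, trials, choices) {
  spec <- as_model_spec(model)
  to_params <- function(th) {
    beta <- exp(th[1]); alpha <- exp(th[2])
    ocu <- if ("ocu" %in% spec$hier_params) th[3] else 0
    if (spec$name == "hybrid") {
      e <- exp(c(th[4], th[5], 0)); w <- e / sum(e)
    } else if (spec$name == "ocu_free") {
      wf <- plogis(th[3]); w <- c(wf, 1 - wf, 0)
    } else w <- c(0, 0, 1)
    agent_parameters(beta, alpha, ocu, w[1], w[2], w[3])
  }
  nll <- function(th) {
    p <- try(to_params(th), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    neg_log_likelihood(spec, trials, choices, p)
  }
  n_th <- switch(spec$name, solo_rp = 2L, ocu = 3L, ocu_free = 3L, hybrid = 5L)
  grid_b <- log(c(0.5, 2, 8)); grid_a <- log(c(0.5, 0.9, 1.3))
  starts <- expand.grid(grid_b, grid_a)
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    th0 <- c(as.numeric(starts[r, ]), rep(0, n_th - 2L))
    o <- optim(th0, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(params = to_params(best$par), neg_ll = best$value)
}
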