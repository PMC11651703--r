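# Monte-Carlo marginal log-likelihood of one subject under the fitted
# group-level distribution: average the choice likelihood over K parameter
# draws (log-sum-exp for stability).
subject_marginal_loglik <- function(spec, trials, choices, hyper, K,
                                    clamp = 1e-9) {
  la <- rnorm(K, hyper$mu_a, hyper$sig_a)
  lb <- rnorm(K, hyper$mu_b, hyper$sig_b)
  alpha <- exp(la); beta <- exp(lb)
  ocu <- if ("ocu" %in% spec$hier_params) rnorm(K, hyper$mu_o, hyper$sig_o)
         else numeric(K)
  pow_mat <- function(v) exp(outer(log(v), alpha))       # n_trials x K
  U_s <- trials$p_high * pow_mat(trials$v_high_safe) +
         (1 - trials$p_high) * pow_mat(trials$v_low_safe)
  U_r <- trials$p_high * pow_mat(trials$v_high_risky) +
         (1 - trials$p_high) * pow_mat(trials$v_low_risky)
  du <- U_s - U_r
  arg <- sweep(du + outer(trials$delta, ocu), 2, beta, `*`)
  pocu <- plogis(arg)
  if (spec$name == "hybrid") {
    e <- matrix(-log(runif(3 * K)), K, 3); w <- e / rowSums(e)
    fs <- trials$trial_type == "INFO_SAFE"
    fr <- trials$trial_type == "INFO_RISKY"
    p <- pocu
    p[fs, ] <- matrix(w[, 1], sum(fs), K, byrow = TRUE) +
               sweep(pocu[fs, , drop = FALSE], 2, w[, 3], `*`)
    p[fr, ] <- matrix(w[, 2], sum(fr), K, byrow = TRUE) +
               sweep(pocu[fr, , drop = FALSE], 2, w[, 3], `*`)
  } else if (spec$name == "ocu_free") {
    wf <- runif(K)
    fs <- trials$trial_type == "INFO_SAFE"
    fr <- trials$trial_type == "INFO_RISKY"
    p <- pocu  # delta = 0 path equals the solo probability here (ocu = 0)
    p[fs, ] <- matrix(wf, sum(fs), K, byrow = TRUE)
    p[fr, ] <- matrix(1 - wf, sum(fr), K, byrow = TRUE)
  } else p <- pocu
  p <- pmin(pmax(p, clamp), 1 - clamp)
  ll <- colSums(log(p) * choices + log1p(-p) * (1 - choices))
  m <- max(ll)
  m + log(mean(exp(ll - m)))
}

fit_hyper_list <- function(fit, group) {
  h <- setNames(fit$hyper$median, fit$hyper$param)
  out <- list(mu_b = h[["mu_b"]], sig_b = h[["sig_b"]],
              mu_a = h[["mu_a"]], sig_a = h[["sig_a"]],
              mu_o = if ("mu_o" %in% names(h)) h[["mu_o"]] else 0,
              sig_o = if ("sig_o" %in% names(h)) h[["sig_o"]] else 1)
  if (!is.null(fit$group_diff)) {
    nm <- paste0("d_logbeta_", group)
    if (nm %in% names(fit$group_diff))
      out$mu_b <- out$mu_b + median(fit$group_diff[[nm]])
  }
  out
}

#' Integrated BIC of a fitted model
#'
#' For each subject, the marginal likelihood of their choices is estimated
#' by Monte Carlo: averaging the likelihood over `n_prior_samples` parameter
#' draws from the fitted group-level distribution (posterior-median
#' hyperparameters, including the subject's group-difference offset;
#' simplex weights drawn uniformly, matching their flat individual-level
#' prior).  The integrated BIC is
#' `-2 * sum_i log m_i + n_free * log(n_total_choices)`,
#' where `n_free` is the model's group-level free-parameter roster (4, 6,
#' 5, 8 for solo_rp / ocu / ocu_free / hybrid) plus any estimated
#' group-difference offsets.  Lower is better.
#'
#' @param model Model name or spec (must match `fit`).
#' @param dataset Choice dataset.
#' @param fit The `hb_fit` of this model on this dataset.
#' @param n_prior_samples Monte-Carlo draws per subject (default 2000;
#'   fewer than 100 draws triggers a high-variance warning).
#' @param seed Optional integer seed.
#' @return An `ibic_result` list: `ibic`, `marginal_loglik`, `penalty`,
#'   `n_free`, `n_prior_samples`, per-subject log marginals.
#' @export
compute_ibic <- function(model, dataset, fit, n_prior_samples = 2000,
                         seed = NULL) {
  spec <- as_model_spec(model)
  if (n_prior_samples < 100)
    warning("n_prior_samples < 100: marginal-likelihood estimate is noisy",
            call. = FALSE)
  ids <- unique(dataset$subject_id)
  with_seed(seed, {
    lm_i <- vapply(ids, function(id) {
      d <- dataset[dataset$subject_id == id, , drop = FALSE]
      grp <- if ("group" %in% names(d)) as.character(d$group[1]) else "ALL"
      subject_marginal_loglik(spec, d, d$choice,
                              fit_hyper_list(fit, grp), n_prior_samples)
    }, numeric(1))
    n_offsets <- length(fit$group_diff)
    n_free <- spec$n_free + n_offsets
    penalty <- n_free * log(nrow(dataset))
    structure(list(model = spec$name, marginal_loglik = sum(lm_i),
                   penalty = penalty, ibic = -2 * sum(lm_i) + penalty,
                   n_free = n_free, n_prior_samples = n_prior_samples,
                   subject_loglik = setNames(lm_i, ids)),
              class = "ibic_result")
  })
}

#' @export
print.ibic_result <- function(x, ...) {
  cat(sprintf("<ibic_result> %s: iBIC = %.1f (logL = %.1f, penalty = %.1f, k = %d, K = %d)\n",
              x$model, x$ibic, x$marginal_loglik, x$penalty, x$n_free,
              x$n_prior_samples))
  invisible(x)
}

#' Default truth distribution for the recovery protocols
#'
#' Population the recovery simulations draw "true" agents from: log inverse
#' temperature `Normal(1.1, 0.8)`, log risk preference `Normal(-0.2, 0.35)`,
#' OCU `Normal(0.2, 0.8)`, and weights uniform on the simplex inside the
#' box follow <= 0.9, oppose <= 0.6, utility in [0.05, 1] -- a spread wide
#' enough to cover utility-dominant and heuristic-dominant agents.
#'
#' @param n_subjects Number of simulated subjects (default 44).
#' @return A [group_spec()].
#' @export
recovery_spec <- function(n_subjects = 44) {
  group_spec("NC", n_subjects,
             mu_log_beta = 1.1, sd_log_beta = 0.8,
             mu_log_alpha = -0.2, sd_log_alpha = 0.35,
             mu_ocu = 0.2, sd_ocu = 0.8,
             w_box = rbind(lo = c(0, 0, 0.05), hi = c(0.9, 0.6, 1)))
}

#' Parameter-recovery protocol for the hybrid model
#'
#' Samples `n_subjects` true parameter sets, simulates their 96-trial
#' sessions under the hybrid model (re-sampling any agent whose simulated
#' behavior hits the exclusion rules), refits the hierarchical hybrid
#' model, and correlates truth with posterior medians for six quantities:
#' log inverse temperature, risk preference, normalized OCU (the logistic
#' `1/(1+exp(-beta*ocu))` using each subject's own beta on both sides), and
#' the three simplex weights.
#'
#' @param n_subjects Simulated sample size (default 44).
#' @param spec Truth distribution ([recovery_spec()] by default).
#' @param mcmc An [mcmc_config()]; reduced draws are standard here.
#' @param seed Integer seed for truth sampling, simulation and chains.
#' @param menus Menu set.
#' @param betas Optional fixed per-subject inverse temperatures.
#' @return A `recovery_report`: `$correlations` (quantity, r, p), `$truth`,
#'   `$estimates`, `$fit`.
#' @export
run_parameter_recovery <- function(n_subjects = 44, spec = recovery_spec(n_subjects),
                                   mcmc = mcmc_config(n_chains = 4, n_draws = 1500,
                                                      n_burnin = 500, seed = 1),
                                   seed = 1, menus = make_menu_set(),
                                   betas = NULL) {
  spec$n_subjects <- n_subjects
  dataset <- simulate_until_valid(spec, "hybrid", seed = seed, menus = menus,
                                  betas = betas, subject_prefix = "R")
  truth <- attr(dataset, "truth")
  fit <- fit_hierarchical("hybrid", dataset, mcmc = mcmc,
                          group_map = setNames(rep("ALL", n_subjects),
                                               truth$subject_id))
  est <- median_params(fit)
  est <- est[match(truth$subject_id, est$subject_id), ]
  pairs <- list(
    log_beta  = cbind(log(truth$beta), log(est$beta)),
    alpha     = cbind(truth$alpha, est$alpha),
    ocu_norm  = cbind(normalized_ocu(truth$beta, truth$ocu),
                      normalized_ocu(est$beta, est$ocu)),
    w_follow  = cbind(truth$w_follow, est$w_follow),
    w_oppose  = cbind(truth$w_oppose, est$w_oppose),
    w_utility = cbind(truth$w_utility, est$w_utility))
  cors <- do.call(rbind, lapply(names(pairs), function(nm) {
    ct <- cor.test(pairs[[nm]][, 1], pairs[[nm]][, 2])
    data.frame(quantity = nm, r = unname(ct$estimate), p = ct$p.value)
  }))
  structure(list(correlations = cors, truth = truth, estimates = est,
                 fit = fit, n_resampled = attr(dataset, "n_resampled")),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", nrow(x$truth), "simulated subjects,",
      x$n_resampled, "resampled during exclusion screening\n")
  print(transform(x$correlations, r = round(r, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

# per-subject best-fit criterion: marginal likelihood under the fitted group
# prior with a subject-grain BIC penalty (individual free-parameter count x
# log n_trials)
subject_fit_scores <- function(fits, ibics, dataset) {
  ids <- unique(dataset$subject_id)
  n_i <- table(dataset$subject_id)[ids]
  scores <- sapply(names(fits), function(m) {
    k <- model_spec(m)$n_free_subject
    -2 * ibics[[m]]$subject_loglik[ids] + k * log(as.numeric(n_i))
  })
  rownames(scores) <- ids
  scores
}

#' Model-recovery protocol (confusion and inversion matrices)
#'
#' Simulates cohorts from each model in `models`, fits every model to every
#' simulated cohort, and summarises recovery three ways: a simulated-by-fit
#' table of group-level iBIC values; a confusion matrix of the proportion
#' of simulated subjects best fit by each model (rows sum to 1); and the
#' inversion matrix (best-fit counts renormalized by column).  The
#' per-subject best-fit criterion is the subject's marginal likelihood
#' under the fitted group prior with a BIC-style penalty (individual
#' free-parameter count times log of the subject's trial count).
#'
#' @param models Models to cross (default all four).
#' @param n_subjects Subjects per simulated cohort.
#' @param spec Truth distribution for the simulated agents.
#' @param mcmc MCMC settings for every fit.
#' @param seed Integer seed.
#' @param menus Menu set.
#' @param n_prior_samples Monte-Carlo draws for the marginal likelihoods.
#' @return A `model_recovery` object: `$ibic_table`, `$confusion`,
#'   `$inversion`, `$best_counts`, `$nonconverged` (sim/fit cells whose
#'   chains failed the R-hat check).
#' @export
run_model_recovery <- function(models = MODEL_NAMES, n_subjects = 44,
                               spec = recovery_spec(n_subjects),
                               mcmc = mcmc_config(n_chains = 2, n_draws = 1200,
                                                  n_burnin = 400, seed = 1),
                               seed = 1, menus = make_menu_set(),
                               n_prior_samples = 2000) {
  spec$n_subjects <- n_subjects
  ibic_table <- matrix(NA_real_, length(models), length(models),
                       dimnames = list(simulated = models, fit = models))
  best_counts <- matrix(0, length(models), length(models),
                        dimnames = list(simulated = models, fit = models))
  nonconv <- NULL
  for (si in seq_along(models)) {
    sim_m <- models[si]
    dataset <- simulate_until_valid(spec, sim_m, seed = seed + 1000L * si,
                                    menus = menus,
                                    subject_prefix = paste0("M", si, "_"))
    fits <- list(); ibics <- list()
    for (fi in seq_along(models)) {
      fit_m <- models[fi]
      cfg <- mcmc; cfg$seed <- mcmc$seed + 17L * si + fi
      f <- suppressWarnings(
        fit_hierarchical(fit_m, dataset, mcmc = cfg,
                         group_map = setNames(rep("ALL", n_subjects),
                                              unique(dataset$subject_id))))
      if (!f$converged)
        nonconv <- rbind(nonconv, data.frame(simulated = sim_m, fit = fit_m,
                                             max_rhat = max(f$rhat)))
      fits[[fit_m]] <- f
      ibics[[fit_m]] <- compute_ibic(fit_m, dataset, f,
                                     n_prior_samples = n_prior_samples,
                                     seed = seed + 7L * fi + si)
      ibic_table[si, fi] <- ibics[[fit_m]]$ibic
    }
    sc <- subject_fit_scores(fits, ibics, dataset)
    best <- models[apply(sc, 1, which.min)]
    best_counts[si, ] <- as.numeric(table(factor(best, levels = models)))
  }
  confusion <- best_counts / rowSums(best_counts)
  inv <- sweep(best_counts, 2, pmax(colSums(best_counts), 1), `/`)
  structure(list(ibic_table = ibic_table, confusion = confusion,
                 inversion = inv, best_counts = best_counts,
                 nonconverged = nonconv),
            class = "model_recovery")
}

#' @export
print.model_recovery <- function(x, ...) {
  cat("<model_recovery> group-level iBIC (rows = simulated, cols = fit):\n")
  print(round(x$ibic_table, 1))
  cat("confusion matrix (row proportions):\n")
  print(round(x$confusion, 2))
  if (!is.null(x$nonconverged)) {
    cat("non-converged cells:\n"); print(x$nonconverged)
  }
  invisible(x)
}
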