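# shared fixtures: tiny sessions, agents and MCMC settings used across tests

hl_pair <- function(p_high = 0.6) {
  # classic Holt-Laury quadruple as a one-trial SOLO table
  data.frame(subject_id = "t", trial_index = 1L, menu_id = 1L, p_high = p_high,
             v_high_safe = 2.00, v_low_safe = 1.60,
             v_high_risky = 3.85, v_low_risky = 0.10,
             trial_type = "SOLO", delta = 0L)
}

info_trial <- function(type, p_high = 0.6) {
  t <- hl_pair(p_high)
  t$trial_type <- type
  t$delta <- ifelse(type == "INFO_SAFE", 1L, ifelse(type == "INFO_RISKY", -1L, 0L))
  t
}

random_params <- function() {
  e <- -log(runif(3)); w <- e / sum(e)
  agent_parameters(beta = exp(rnorm(1, 1, 0.7)), alpha = exp(rnorm(1, -0.2, 0.3)),
                   ocu = rnorm(1, 0, 0.8),
                   w_follow = w[1], w_oppose = w[2], w_utility = w[3])
}

random_trial <- function() {
  type <- sample(c("SOLO", "INFO_SAFE", "INFO_RISKY", "INFO_MIX"), 1)
  scale <- runif(1, 0.5, 3)
  t <- info_trial(type, p_high = sample(seq(0.4, 0.9, 0.1), 1))
  for (v in c("v_high_safe", "v_low_safe", "v_high_risky", "v_low_risky"))
    t[[v]] <- t[[v]] * scale
  t
}

tiny_mcmc <- function(seed = 1)
  mcmc_config(n_chains = 2, n_draws = 700, n_burnin = 250, n_adapt = 200,
              seed = seed)

# brute-force Bernoulli-product negative log likelihood (independent oracle)
brute_force_nll <- function(model, trials, choices, params) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    p <- p_safe(model, trials[i, , drop = FALSE], params)
    p <- min(max(p, 1e-9), 1 - 1e-9)
    total <- total - log(if (choices[i] == 1) p else 1 - p)
  }
  total
}
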