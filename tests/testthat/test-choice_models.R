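test_that("gamble utility matches direct power evaluation", {
  expect_equal(gamble_utility(0.6, 2.0, 1.6, 1), 1.84)          # expected value
  expect_equal(gamble_utility(1.0, 2.0, 0.7, 0.8), 2^0.8)       # certain payoff
  expect_equal(gamble_utility(0.5, 1.3, 1.3, 0.62), 1.3^0.62)   # degenerate lottery
  expect_error(gamble_utility(0.5, -1, 1, 1), "positive")
})

test_that("solo softmax probability matches hand arithmetic", {
  t <- hl_pair(0.6)
  p <- agent_parameters(beta = 1, alpha = 1)
  # U_safe = 1.84, U_risky = 2.35 -> logistic(-0.51)
  expect_equal(p_safe_solo(t, p), 1 / (1 + exp(0.51)), tolerance = 1e-12)
  expect_equal(round(p_safe_solo(t, p), 4), 0.3752)
  # equal utilities -> indifference
  t2 <- t; t2$v_high_risky <- 2.0; t2$v_low_risky <- 1.6
  expect_equal(p_safe_solo(t2, p), 0.5)
  # beta -> 0 limit
  p0 <- agent_parameters(beta = 1e-12, alpha = 1)
  expect_equal(p_safe_solo(t, p0), 0.5, tolerance = 1e-9)
})

test_that("OCU shifts the softmax argument by delta * ocu", {
  tr <- info_trial("INFO_SAFE")
  p <- agent_parameters(beta = 1, alpha = 1, ocu = 0.5)
  expect_equal(p_safe_ocu(tr, p), 1 / (1 + exp(0.01)), tolerance = 1e-12)
  # ocu = 0 reduces to the solo model on any trial type
  p0 <- agent_parameters(beta = 1.7, alpha = 0.8, ocu = 0)
  for (type in c("SOLO", "INFO_SAFE", "INFO_RISKY", "INFO_MIX")) {
    tt <- info_trial(type)
    expect_equal(p_safe_ocu(tt, p0), p_safe_solo(tt, p0))
  }
  # delta = 0 trials ignore ocu entirely
  pbig <- agent_parameters(beta = 1.7, alpha = 0.8, ocu = 5)
  for (type in c("SOLO", "INFO_MIX"))
    expect_equal(p_safe_ocu(info_trial(type), pbig),
                 p_safe_solo(info_trial(type), pbig))
})

test_that("hybrid mixture combines heuristic and utility routes", {
  tr <- info_trial("INFO_SAFE")
  p <- agent_parameters(beta = 1, alpha = 1, ocu = 0.5,
                        w_follow = 0.3, w_oppose = 0.1, w_utility = 0.6)
  pocu <- p_safe_ocu(tr, p)
  expect_equal(p_safe_hybrid(tr, p), 0.3 + 0.6 * pocu, tolerance = 1e-12)
  expect_equal(round(p_safe_hybrid(tr, p), 4), round(0.3 + 0.6 / (1 + exp(0.01)), 4))
  # pure follower is certain to copy, regardless of the gambles
  pf <- agent_parameters(beta = 1, alpha = 1, ocu = 0,
                         w_follow = 1, w_oppose = 0, w_utility = 0)
  expect_equal(p_safe_hybrid(info_trial("INFO_SAFE"), pf), 1)
  expect_equal(p_safe_hybrid(info_trial("INFO_RISKY"), pf), 0)
  expect_error(p_safe_hybrid(tr, list(beta = 1, alpha = 1, ocu = 0,
                                      w_follow = 0.7, w_oppose = 0.7,
                                      w_utility = 0.7)), "simplex")
})

test_that("model nesting holds to numerical precision", {
  set.seed(42)
  for (i in 1:50) {
    pars <- random_params()
    tr <- random_trial()
    # hybrid with w_utility = 1 is the OCU model
    pu <- agent_parameters(pars$beta, pars$alpha, pars$ocu, 0, 0, 1)
    expect_equal(p_safe_hybrid(tr, pu), p_safe_ocu(tr, pu), tolerance = 1e-12)
    # OCU with ocu = 0 is the solo model
    p0 <- agent_parameters(pars$beta, pars$alpha, 0)
    expect_equal(p_safe_ocu(tr, p0), p_safe_solo(tr, p0), tolerance = 1e-12)
  }
})

test_that("heuristic weights bound the hybrid safe-choice probability", {
  set.seed(7)
  for (i in 1:200) {
    pars <- random_params()
    ts <- random_trial(); ts$trial_type <- "INFO_SAFE"; ts$delta <- 1L
    pr <- ts; pr$trial_type <- "INFO_RISKY"; pr$delta <- -1L
    ps <- p_safe_hybrid(ts, pars)
    expect_gte(ps, pars$w_follow); expect_lte(ps, 1 - pars$w_oppose)
    pk <- p_safe_hybrid(pr, pars)
    expect_gte(pk, pars$w_oppose); expect_lte(pk, 1 - pars$w_follow)
  }
})

test_that("safe-choice probability on unanimous-safe trials rises with OCU", {
  tr <- info_trial("INFO_SAFE")
  ocus <- seq(-2, 2, 0.25)
  ps <- vapply(ocus, function(o)
    p_safe_ocu(tr, agent_parameters(1.4, 0.9, o)), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("normalized OCU is the logistic of beta * ocu", {
  expect_equal(normalized_ocu(2, 0), 0.5)
  expect_equal(normalized_ocu(1, 0.5), 1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(round(normalized_ocu(1, 0.5), 4), 0.6225)
  expect_equal(normalized_ocu(1, 1e6), 1)
  expect_error(normalized_ocu(-1, 0), "beta")
})

test_that("negative log likelihood matches closed forms and brute force", {
  s <- build_session(make_menu_set(), "s", seed = 3)
  set.seed(1); ch <- rbinom(96, 1, 0.5)
  # an indifferent agent predicts 0.5 everywhere
  p_ind <- agent_parameters(beta = 1e-12, alpha = 1)
  expect_equal(neg_log_likelihood("solo_rp", s, ch, p_ind), 96 * log(2),
               tolerance = 1e-6)
  # perfect follower, all-concordant choices -> zero
  pf <- agent_parameters(1, 1, 0, 1, 0, 0)
  info <- s[s$trial_type %in% c("INFO_SAFE", "INFO_RISKY"), ]
  concordant <- as.numeric(info$trial_type == "INFO_SAFE")
  expect_equal(neg_log_likelihood("hybrid", info, concordant, pf), 0,
               tolerance = 1e-6)
  # clamping keeps one discordant choice finite
  discordant <- concordant; discordant[1] <- 1 - discordant[1]
  nll <- neg_log_likelihood("hybrid", info, discordant, pf)
  expect_true(is.finite(nll))
  expect_equal(nll, -log(1e-9), tolerance = 1e-6)
  # brute-force oracle on a 5-trial toy, all models
  toy <- s[9:13, ]
  set.seed(2); toych <- rbinom(5, 1, 0.5)
  for (m in c("solo_rp", "ocu", "ocu_free", "hybrid")) {
    pars <- random_params()
    expect_equal(neg_log_likelihood(m, toy, toych, pars),
                 brute_force_nll(m, toy, toych, pars), tolerance = 1e-10)
  }
  expect_error(neg_log_likelihood("solo_rp", toy, c(1, 0), random_params()),
               "misaligned")
})

test_that("trial filtering restricts the likelihood to selected types", {
  s <- build_session(make_menu_set(), "s", seed = 8)
  set.seed(3); ch <- rbinom(96, 1, 0.5)
  pars <- agent_parameters(2, 0.8)
  solo <- s$trial_type == "SOLO"
  expect_equal(neg_log_likelihood("solo_rp", s, ch, pars, trial_filter = "SOLO"),
               neg_log_likelihood("solo_rp", s[solo, ], ch[solo], pars))
})

test_that("model specs expose the documented free-parameter rosters", {
  expect_equal(model_spec("solo_rp")$n_free, 4)
  expect_equal(model_spec("ocu")$n_free, 6)
  expect_equal(model_spec("ocu_free")$n_free, 5)
  expect_equal(model_spec("hybrid")$n_free, 8)
  expect_error(model_spec("prospect"))
})
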