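test_that("agents are drawn from the group hyperdistributions", {
  spec <- group_spec("NC", 400, mu_log_beta = 1, sd_log_beta = 0.5,
                     mu_log_alpha = -0.2, sd_log_alpha = 0.25,
                     mu_ocu = 0.3, sd_ocu = 0.6)
  a <- sample_agents(spec, seed = 4)
  expect_equal(nrow(a), 400)
  expect_equal(mean(log(a$beta)), 1, tolerance = 0.1)
  expect_equal(sd(log(a$beta)), 0.5, tolerance = 0.1)
  expect_equal(mean(a$ocu), 0.3, tolerance = 0.12)
  expect_true(all(abs(a$w_follow + a$w_oppose + a$w_utility - 1) < 1e-12))
  # degenerate SDs give identical agents
  spec0 <- group_spec("NC", 5, 1, 0, -0.2, 0, 0.3, 0)
  a0 <- sample_agents(spec0, seed = 1)
  expect_equal(unique(round(a0$beta, 10)), exp(1))
  expect_equal(unique(round(a0$alpha, 10)), exp(-0.2))
})

test_that("unrestricted simplex sampling has flat-Dirichlet moments", {
  spec <- group_spec("NC", 10000, 1, 0.5, 0, 0.2, 0, 0.5)
  a <- sample_agents(spec, seed = 9)
  # Dirichlet(1,1,1) oracle: each component has mean 1/3, var 1/18
  expect_equal(mean(a$w_follow), 1 / 3, tolerance = 0.01)
  expect_equal(mean(a$w_oppose), 1 / 3, tolerance = 0.01)
  expect_equal(mean(a$w_utility), 1 / 3, tolerance = 0.01)
  expect_equal(var(a$w_follow), 1 / 18, tolerance = 0.005)
})

test_that("infeasible weight boxes are rejected at spec construction", {
  expect_error(group_spec("NC", 5, 1, 0.5, 0, 0.2, 0, 0.5,
                          w_box = rbind(lo = c(0.9, 0.2, 0), hi = c(1, 1, 1))),
               "infeasible")
})

test_that("weight boxes actually constrain the draws", {
  box <- rbind(lo = c(0.5, 0, 0), hi = c(1, 0.3, 0.5))
  spec <- group_spec("INSULA", 500, 1, 0.5, 0, 0.2, 0, 0.5, w_box = box)
  a <- sample_agents(spec, seed = 2)
  expect_true(all(a$w_follow >= 0.5 & a$w_oppose <= 0.3 & a$w_utility <= 0.5))
})

test_that("simulated choices follow the generating probabilities", {
  # a pure follower copies unanimous others deterministically
  ag <- data.frame(group = "NC", beta = 2, alpha = 1, ocu = 0,
                   w_follow = 1, w_oppose = 0, w_utility = 0)
  d <- simulate_choices(ag, "hybrid", seed = 5)
  expect_equal(nrow(d), 96)
  expect_true(all(d$choice[d$trial_type == "INFO_SAFE"] == 1))
  expect_true(all(d$choice[d$trial_type == "INFO_RISKY"] == 0))
  # a near-deterministic EV maximizer follows the sign of the EV difference
  ag2 <- data.frame(group = "NC", beta = 500, alpha = 1, ocu = 0,
                    w_follow = 0, w_oppose = 0, w_utility = 1)
  d2 <- simulate_choices(ag2, "hybrid", seed = 6)
  solo <- d2[d2$trial_type == "SOLO", ]
  ev_diff <- gamble_utility(solo$p_high, solo$v_high_safe, solo$v_low_safe, 1) -
    gamble_utility(solo$p_high, solo$v_high_risky, solo$v_low_risky, 1)
  expect_equal(solo$choice, as.numeric(ev_diff > 0))
})

test_that("empirical choice rates converge to the analytic probability", {
  tr <- info_trial("INFO_SAFE")
  pars <- agent_parameters(1.2, 0.9, 0.4, 0.25, 0.05, 0.7)
  p_true <- p_safe_hybrid(tr, pars)
  ag <- data.frame(group = "NC", beta = 1.2, alpha = 0.9, ocu = 0.4,
                   w_follow = 0.25, w_oppose = 0.05, w_utility = 0.7)
  reps <- 10000
  sess <- do.call(rbind, replicate(reps, tr, simplify = FALSE))
  sess$subject_id <- "S001"; sess$trial_index <- seq_len(reps)
  d <- simulate_choices(ag, "hybrid", sessions = sess, seed = 11)
  expect_lt(abs(mean(d$choice) - p_true), 0.01)
})

test_that("exclusion rules flag reversals and degenerate solo behavior", {
  menus <- make_menu_set()
  mk <- function(id, choice_fun) {
    s <- build_session(menus, id, seed = match(id, c("a", "b", "c")) + 10)
    s$group <- "NC"; s$choice <- choice_fun(s); s
  }
  all_safe <- mk("a", function(s) rep(1L, nrow(s)))
  # monotone-consistent: risky when p high, safe when p low, mixed solo
  consistent <- mk("b", function(s) as.integer(s$p_high < 0.7))
  # reversal: risky at low p, safe at high p
  reversed <- mk("c", function(s) as.integer(s$p_high >= 0.7))
  d <- rbind(all_safe, consistent, reversed)
  res <- apply_exclusions(d)
  expect_setequal(res$excluded, c("a", "c"))
  expect_true(res$report$rule_degenerate_solo[res$report$subject_id == "a"])
  expect_true(res$report$rule_reversal[res$report$subject_id == "c"])
  expect_false(any(res$report$excluded[res$report$subject_id == "b"]))
  # purity: re-running on the kept set excludes no one
  res2 <- apply_exclusions(res$kept)
  expect_length(res2$excluded, 0)
})

test_that("resampling returns exactly n included subjects with truth attached", {
  spec <- default_cohort_spec(6, 3, 2)$NC
  d <- simulate_until_valid(spec, "hybrid", seed = 21)
  expect_equal(length(unique(d$subject_id)), 6)
  expect_length(apply_exclusions(d)$excluded, 0)
  truth <- attr(d, "truth")
  expect_equal(nrow(truth), 6)
  expect_setequal(truth$subject_id, unique(d$subject_id))
})

test_that("lesion-like cohorts show the conformity direction", {
  spec <- default_cohort_spec()$INSULA
  spec$n_subjects <- 40
  d <- simulate_until_valid(spec, "hybrid", seed = 31)
  rate <- function(type) mean(d$choice[d$trial_type == type] == 1)
  expect_gt(rate("INFO_SAFE"), rate("SOLO"))
  expect_lt(rate("INFO_RISKY"), rate("SOLO"))
})
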