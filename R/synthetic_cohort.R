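GROUP_LABELS <- c("NC", "INSULA", "DACC")

#' Group specification for the synthetic cohort
#'
#' Describes one participant group: how many subjects, the group-level
#' distributions for log inverse temperature, log risk preference and OCU
#' (individual values are drawn `Normal(mean, sd)` on those scales), and a
#' range box restricting the uniform-simplex draw of the mixture weights.
#'
#' @param label Group label, one of `"NC"`, `"INSULA"`, `"DACC"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param mu_log_beta,sd_log_beta Mean/SD of log inverse temperature.
#' @param mu_log_alpha,sd_log_alpha Mean/SD of log risk preference.
#' @param mu_ocu,sd_ocu Mean/SD of other-conferred utility.
#' @param w_box 2 x 3 matrix (rows `lo`, `hi`; columns follow, oppose,
#'   utility) bounding each weight; weights are sampled uniformly on the
#'   simplex and rejection-sampled into the box.
#' @return A `group_spec` object.
#' @export
group_spec <- function(label, n_subjects,
                       mu_log_beta, sd_log_beta,
                       mu_log_alpha, sd_log_alpha,
                       mu_ocu, sd_ocu,
                       w_box = rbind(lo = c(0, 0, 0), hi = c(1, 1, 1))) {
  label <- match.arg(label, GROUP_LABELS)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(c(sd_log_beta, sd_log_alpha, sd_ocu) < 0))
    stop("hyper SDs must be >= 0", call. = FALSE)
  w_box <- as.matrix(w_box)
  if (!all(dim(w_box) == c(2, 3)) || any(w_box < 0) || any(w_box > 1) ||
      any(w_box[1, ] > w_box[2, ]))
    stop("w_box must be a 2 x 3 matrix of bounds within [0, 1]", call. = FALSE)
  if (sum(w_box[1, ]) > 1 + 1e-12 || sum(w_box[2, ]) < 1 - 1e-12)
    stop("weight range box excludes the whole simplex (infeasible)", call. = FALSE)
  colnames(w_box) <- c("w_follow", "w_oppose", "w_utility")
  structure(list(label = label, n_subjects = n_subjects,
                 mu_log_beta = mu_log_beta, sd_log_beta = sd_log_beta,
                 mu_log_alpha = mu_log_alpha, sd_log_alpha = sd_log_alpha,
                 mu_ocu = mu_ocu, sd_ocu = sd_ocu, w_box = w_box),
            class = "group_spec")
}

#' Default three-group cohort specification
#'
#' The study conditions the simulator emulates: a non-lesion control group
#' and two lesion-like groups (insula-like, dACC-like).  Lesion-like groups
#' have a lower inverse temperature (noisier utility-based choice) and a
#' weight box shifted toward the follow heuristic and away from the utility
#' route; controls are utility-dominant.  Group sizes default to the
#' analyzed sample (28 / 10 / 6).
#'
#' @param n_nc,n_insula,n_dacc Group sizes.
#' @return Named list of three [group_spec()] objects.
#' @export
default_cohort_spec <- function(n_nc = 28, n_insula = 10, n_dacc = 6) {
  nc <- group_spec("NC", n_nc,
                   mu_log_beta = log(4), sd_log_beta = 0.7,
                   mu_log_alpha = log(0.85), sd_log_alpha = 0.35,
                   mu_ocu = 0.25, sd_ocu = 0.75,
                   w_box = rbind(lo = c(0, 0, 0.30), hi = c(0.50, 0.30, 1)))
  lesion_box <- rbind(lo = c(0.25, 0, 0.05), hi = c(0.90, 0.30, 0.60))
  ins <- group_spec("INSULA", n_insula,
                    mu_log_beta = log(2), sd_log_beta = 0.7,
                    mu_log_alpha = log(0.85), sd_log_alpha = 0.35,
                    mu_ocu = 0.25, sd_ocu = 0.75, w_box = lesion_box)
  dacc <- ins; dacc$label <- "DACC"; dacc$n_subjects <- n_dacc
  list(NC = nc, INSULA = ins, DACC = dacc)
}

# Uniform draw from the unit simplex (flat Dirichlet), rejected into a box.
sample_simplex_box <- function(n, w_box, max_rej = 1e5) {
  out <- matrix(NA_real_, n, 3)
  filled <- 0L; tries <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 64L)
    e <- matrix(-log(runif(3L * m)), m, 3)
    w <- e / rowSums(e)
    ok <- w[, 1] >= w_box[1, 1] & w[, 1] <= w_box[2, 1] &
          w[, 2] >= w_box[1, 2] & w[, 2] <= w_box[2, 2] &
          w[, 3] >= w_box[1, 3] & w[, 3] <= w_box[2, 3]
    k <- min(sum(ok), n - filled)
    if (k > 0) {
      out[filled + seq_len(k), ] <- w[which(ok)[seq_len(k)], , drop = FALSE]
      filled <- filled + k
    }
    tries <- tries + m
    if (tries > max_rej && filled == 0L)
      stop("weight range box appears infeasible on the simplex", call. = FALSE)
    if (tries > 100 * max_rej)
      stop("weight box acceptance rate too low", call. = FALSE)
  }
  colnames(out) <- c("w_follow", "w_oppose", "w_utility")
  out
}

#' Sample agent parameters from a group specification
#'
#' Inverse temperature and risk preference are drawn log-normally, OCU
#' normally, and the three mixture weights uniformly on the unit simplex
#' restricted to the spec's range box.
#'
#' @param spec A [group_spec()].
#' @param seed Optional integer seed.
#' @param betas Optional vector of fixed inverse temperatures (length
#'   `n_subjects`), used when emulating a protocol that reuses known
#'   per-subject betas instead of sampling them.
#' @return Data frame of true parameters, one row per agent, with columns
#'   `group`, `beta`, `alpha`, `ocu`, `w_follow`, `w_oppose`, `w_utility`.
#' @export
sample_agents <- function(spec, seed = NULL, betas = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  n <- spec$n_subjects
  with_seed(seed, {
    beta <- if (is.null(betas)) exp(rnorm(n, spec$mu_log_beta, spec$sd_log_beta))
            else rep_len(betas, n)
    alpha <- exp(rnorm(n, spec$mu_log_alpha, spec$sd_log_alpha))
    ocu <- rnorm(n, spec$mu_ocu, spec$sd_ocu)
    w <- sample_simplex_box(n, spec$w_box)
    data.frame(group = spec$label, beta = beta, alpha = alpha, ocu = ocu,
               w_follow = w[, 1], w_oppose = w[, 2], w_utility = w[, 3])
  })
}

agent_row_params <- function(agents, i) {
  agent_parameters(beta = agents$beta[i], alpha = agents$alpha[i],
                   ocu = agents$ocu[i], w_follow = agents$w_follow[i],
                   w_oppose = agents$w_oppose[i], w_utility = agents$w_utility[i])
}

#' Simulate a choice dataset from a set of agents
#'
#' Builds one randomized session per agent (or reuses supplied sessions) and
#' draws each choice `Bernoulli(P_safe)` under the given model.  The true
#' parameters travel with the dataset as the `"truth"` attribute.
#'
#' @param agents Data frame from [sample_agents()] (rows may span groups).
#' @param model Model used to generate choices (default `"hybrid"`).
#' @param menus Menu set (default [make_menu_set()]).
#' @param sessions Optional prebuilt trial table covering every subject.
#' @param seed Optional integer seed.
#' @param subject_ids Optional character ids (default `"S001"...`).
#' @return Trial-level data frame with added `group` and `choice` columns
#'   (1 = safer gamble chosen); `attr(, "truth")` holds the agents with ids.
#' @export
simulate_choices <- function(agents, model = "hybrid", menus = make_menu_set(),
                             sessions = NULL, seed = NULL, subject_ids = NULL) {
  n <- nrow(agents)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      tr <- if (is.null(sessions)) build_session(menus, subject_ids[i]) else {
        s <- sessions[sessions$subject_id == subject_ids[i], , drop = FALSE]
        if (!nrow(s)) stop("no session rows for subject ", subject_ids[i], call. = FALSE)
        s
      }
      p <- p_safe(model, tr, agent_row_params(agents, i))
      tr$group <- agents$group[i]
      tr$choice <- rbinom(nrow(tr), 1, p)
      rows[[i]] <- tr
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    truth <- cbind(subject_id = subject_ids, agents)
    attr(out, "truth") <- truth
    out
  })
}

risky_rate_at <- function(d, p) {
  sub <- d[abs(d$p_high - p) < 1e-9, , drop = FALSE]
  if (!nrow(sub)) return(NA_real_)
  mean(sub$choice == 0)
}

#' Apply the a-priori behavioral exclusion rules
#'
#' Two rules, mirroring the study's screening of participants:
#' (i) subjects whose riskier-choice proportion at the highest win
#' probability (0.9) is strictly lower than at the lowest (0.4) -- i.e. who
#' chose the option with the greater high payoff *less* often as winning
#' became more likely -- are excluded (ties keep); (ii) subjects who chose
#' all-safe or all-risky on every Solo trial are excluded, since
#' bi-directional social influence is impossible for them.
#'
#' @param dataset Choice dataset in the [simulate_choices()] schema.
#' @param rule1_trials `"all"` (default) to evaluate rule (i) on all trials,
#'   `"solo"` to restrict it to Solo trials (sensitivity variant).
#' @return List with `kept` (dataset of surviving subjects), `report`
#'   (per-subject data frame of rule hits) and `excluded` (ids).
#' @export
apply_exclusions <- function(dataset, rule1_trials = c("all", "solo")) {
  rule1_trials <- match.arg(rule1_trials)
  ids <- unique(dataset$subject_id)
  rep_rows <- lapply(ids, function(id) {
    d <- dataset[dataset$subject_id == id, , drop = FALSE]
    d1 <- if (rule1_trials == "solo") d[d$trial_type == "SOLO", , drop = FALSE] else d
    r_lo <- risky_rate_at(d1, 0.4)
    r_hi <- risky_rate_at(d1, 0.9)
    if (is.na(r_lo) || is.na(r_hi))
      stop("subject ", id, " lacks trials at probability 0.4 or 0.9", call. = FALSE)
    solo <- d$choice[d$trial_type == "SOLO"]
    rule1 <- r_hi < r_lo
    rule2 <- length(solo) > 0 && (all(solo == 1) || all(solo == 0))
    data.frame(subject_id = id, risky_rate_p40 = r_lo, risky_rate_p90 = r_hi,
               rule_reversal = rule1, rule_degenerate_solo = rule2,
               excluded = rule1 || rule2)
  })
  report <- do.call(rbind, rep_rows)
  keep_ids <- report$subject_id[!report$excluded]
  kept <- dataset[dataset$subject_id %in% keep_ids, , drop = FALSE]
  truth <- attr(dataset, "truth")
  if (!is.null(truth))
    attr(kept, "truth") <- truth[truth$subject_id %in% keep_ids, , drop = FALSE]
  list(kept = kept, report = report, excluded = report$subject_id[report$excluded])
}

#' Simulate a cohort until every subject passes the exclusion rules
#'
#' Draws agents and simulates their sessions; any agent whose simulated
#' behavior hits an exclusion rule is replaced by a freshly sampled agent
#' and re-simulated, so the returned dataset contains exactly
#' `spec$n_subjects` included subjects (the resampling rule the recovery
#' protocols rely on).
#'
#' @inheritParams sample_agents
#' @param model Generating model.
#' @param menus Menu set.
#' @param max_tries Maximum resampling rounds (error if exhausted).
#' @param subject_prefix Prefix for subject ids.
#' @return Choice dataset (with `"truth"` and `"n_resampled"` attributes).
#' @export
simulate_until_valid <- function(spec, model = "hybrid", seed = NULL,
                                 menus = make_menu_set(), betas = NULL,
                                 max_tries = 50, subject_prefix = spec$label) {
  if (max_tries < 1) stop("max_tries must be >= 1", call. = FALSE)
  with_seed(seed, {
    n <- spec$n_subjects
    ids <- sprintf("%s%03d", subject_prefix, seq_len(n))
    agents <- sample_agents(spec, betas = betas)
    data <- simulate_choices(agents, model, menus, subject_ids = ids)
    n_resampled <- 0L
    for (try in seq_len(max_tries)) {
      bad <- apply_exclusions(data)$excluded
      if (!length(bad)) break
      if (try == max_tries)
        stop("simulate_until_valid: max_tries exhausted with ", length(bad),
             " subjects still excluded", call. = FALSE)
      idx <- match(bad, ids)
      spec_b <- spec; spec_b$n_subjects <- length(bad)
      fresh <- sample_agents(spec_b, betas = if (is.null(betas)) NULL else betas[idx])
      redo <- simulate_choices(fresh, model, menus, subject_ids = bad)
      agents[idx, ] <- fresh
      data <- rbind(data[!data$subject_id %in% bad, , drop = FALSE], redo)
      data <- data[order(match(data$subject_id, ids), data$trial_index), ]
      rownames(data) <- NULL
      attr(data, "truth") <- cbind(subject_id = ids, agents)
      n_resampled <- n_resampled + length(bad)
    }
    attr(data, "n_resampled") <- n_resampled
    data
  })
}
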