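#' Safe-choice curve by win probability
#'
#' Per-subject proportion of safe choices at each win-probability level,
#' optionally restricted to a subset of trial types.  Utility-maximizing
#' behavior makes the curve nonincreasing in the win probability (the
#' riskier gamble's expected-value advantage grows with `p_high` for the
#' menus used here); attenuated slopes indicate disrupted risk sensitivity.
#'
#' @param dataset Choice dataset.
#' @param trial_filter Optional trial types, e.g. `"SOLO"`.
#' @return Data frame `subject_id`, `group`, `p_high`, `p_safe`, `n_trials`.
#' @export
choice_curve <- function(dataset, trial_filter = NULL) {
  d <- dataset
  if (!is.null(trial_filter)) d <- d[d$trial_type %in% trial_filter, , drop = FALSE]
  if (!nrow(d)) stop("no trials left after filtering", call. = FALSE)
  agg <- aggregate(choice ~ subject_id + group + p_high, data = d, FUN = mean)
  cnt <- aggregate(choice ~ subject_id + group + p_high, data = d, FUN = length)
  names(agg)[names(agg) == "choice"] <- "p_safe"
  agg$n_trials <- cnt$choice
  agg[order(agg$subject_id, agg$p_high), ]
}

#' Model-agnostic conformity profile
#'
#' For each subject: `c_safe`, the proportion of safe choices when both
#' others chose safe; `c_risky`, the proportion of risky choices when both
#' others chose risky; the Solo safe rate; and the conformity-tendency
#' distance -- the orthogonal distance from (`c_safe`, `c_risky`) to the
#' line `c_risky = 1 - c_safe`, i.e. `|c_safe + c_risky - 1| / sqrt(2)`.
#' Utility-driven agents sit near the line (following safe advice trades
#' off against following risky advice); heuristic followers or opposers sit
#' far from it in either direction.
#'
#' @param dataset Choice dataset.
#' @param min_trials Minimum trials per Info cell for a profile (default 5);
#'   subjects below it get `NA` distances.
#' @return Data frame `subject_id`, `group`, `c_safe`, `c_risky`,
#'   `solo_safe_rate`, `distance`.
#' @export
conformity_profile <- function(dataset, min_trials = 5) {
  ids <- unique(dataset$subject_id)
  rows <- lapply(ids, function(id) {
    d <- dataset[dataset$subject_id == id, , drop = FALSE]
    safe_tr <- d[d$trial_type == "INFO_SAFE", , drop = FALSE]
    risky_tr <- d[d$trial_type == "INFO_RISKY", , drop = FALSE]
    ok <- nrow(safe_tr) >= min_trials && nrow(risky_tr) >= min_trials
    c_safe <- if (nrow(safe_tr)) mean(safe_tr$choice == 1) else NA_real_
    c_risky <- if (nrow(risky_tr)) mean(risky_tr$choice == 0) else NA_real_
    solo <- d[d$trial_type == "SOLO", , drop = FALSE]
    data.frame(subject_id = id,
               group = if ("group" %in% names(d)) as.character(d$group[1]) else NA,
               c_safe = c_safe, c_risky = c_risky,
               solo_safe_rate = if (nrow(solo)) mean(solo$choice == 1) else NA_real_,
               distance = if (ok) abs(c_safe + c_risky - 1) / sqrt(2) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Correlate conformity distance with fitted heuristic weights
#'
#' Robust (skipped) correlations between the model-agnostic conformity
#' distance and the fitted `w_follow` (expected positive: strong followers
#' sit far from the trade-off line) and `w_oppose` (expected negative)
#' across subjects.
#'
#' @param profiles Output of [conformity_profile()].
#' @param params Per-subject parameter table ([median_params()]).
#' @param n_iter Bootstrap iterations for p values.
#' @param seed Optional integer seed.
#' @return Data frame with one row per weight: `r`, `p`, `n`.
#' @export
validate_weights <- function(profiles, params, n_iter = 2000, seed = NULL) {
  m <- merge(profiles, params, by = "subject_id")
  m <- m[is.finite(m$distance), , drop = FALSE]
  if (nrow(m) < 4) stop("too few complete profiles", call. = FALSE)
  res <- lapply(c("w_follow", "w_oppose"), function(wn) {
    rc <- robust_correlation(m$distance, m[[wn]], n_iter = n_iter, seed = seed)
    data.frame(weight = wn, r = rc$r, p = rc$p, n = nrow(m))
  })
  do.call(rbind, res)
}
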