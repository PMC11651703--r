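#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv
"_PACKAGE"

TRIAL_TYPES <- c("SOLO", "INFO_SAFE", "INFO_RISKY", "INFO_MIX")

# Run expr with a temporarily-seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Classic lottery-menu payoff template
#'
#' The safer/riskier payoff quadruple of the classic Holt--Laury risk
#' elicitation pair: the safer gamble pays 2.00 or 1.60, the riskier
#' 3.85 or 0.10.  All menus generated by [make_menu_set()] are
#' multiplicative rescalings of a template of this form.
#'
#' @return Named numeric vector with elements `v_high_safe`, `v_low_safe`,
#'   `v_high_risky`, `v_low_risky`.
#' @export
default_menu_template <- function() {
  c(v_high_safe = 2.00, v_low_safe = 1.60, v_high_risky = 3.85, v_low_risky = 0.10)
}

validate_menu_template <- function(template) {
  need <- c("v_high_safe", "v_low_safe", "v_high_risky", "v_low_risky")
  if (!all(need %in% names(template)))
    stop("menu template must contain ", paste(need, collapse = ", "), call. = FALSE)
  t <- template[need]
  if (any(t <= 0)) stop("all menu payoffs must be positive", call. = FALSE)
  if (!(t["v_high_risky"] > t["v_high_safe"]))
    stop("invalid menu template: v_high_risky must exceed v_high_safe", call. = FALSE)
  if (!(t["v_low_risky"] < t["v_low_safe"]))
    stop("invalid menu template: v_low_risky must be below v_low_safe", call. = FALSE)
  if (!(t["v_high_safe"] > t["v_low_safe"]))
    stop("invalid menu template: v_high_safe must exceed v_low_safe", call. = FALSE)
  t
}

#' Generate a set of lottery menus
#'
#' Each menu is a payoff quadruple (safer gamble high/low payoff, riskier
#' gamble high/low payoff).  On every trial both gambles share a win
#' probability, so the riskier gamble -- wider payoff spread -- always has the
#' larger payoff variance.  Menus are multiplicative rescalings of `template`,
#' which preserves the spread ordering exactly.
#'
#' @param n_menus Number of menus (default 8).
#' @param template Payoff quadruple, see [default_menu_template()].
#' @param scales Optional numeric vector of length `n_menus` of positive
#'   multipliers; defaults to evenly spaced factors from 1 to 2.75.
#' @return Data frame with columns `menu_id`, `v_high_safe`, `v_low_safe`,
#'   `v_high_risky`, `v_low_risky`.
#' @examples
#' make_menu_set(8)
#' @export
make_menu_set <- function(n_menus = 8, template = default_menu_template(),
                          scales = NULL) {
  if (n_menus < 1) stop("n_menus must be >= 1", call. = FALSE)
  t <- validate_menu_template(template)
  if (is.null(scales)) {
    scales <- if (n_menus == 1) 1 else seq(1, 2.75, length.out = n_menus)
  }
  if (length(scales) != n_menus || any(scales <= 0))
    stop("scales must be ", n_menus, " positive multipliers", call. = FALSE)
  data.frame(
    menu_id      = seq_len(n_menus),
    v_high_safe  = t["v_high_safe"] * scales,
    v_low_safe   = t["v_low_safe"] * scales,
    v_high_risky = t["v_high_risky"] * scales,
    v_low_risky  = t["v_low_risky"] * scales,
    row.names    = NULL
  )
}

#' Payoff variance of a two-outcome gamble
#'
#' @param p_high Win probability of the high payoff.
#' @param v_high,v_low Payoffs.
#' @return Variance `p(1-p)(v_high - v_low)^2`, vectorised.
#' @export
gamble_variance <- function(p_high, v_high, v_low) {
  p_high * (1 - p_high) * (v_high - v_low)^2
}

delta_for_type <- function(trial_type) {
  ifelse(trial_type == "INFO_SAFE", 1L, ifelse(trial_type == "INFO_RISKY", -1L, 0L))
}

#' Build a randomized 96-trial session
#'
#' Selects `n_select` menus without replacement from `menus`, crosses them
#' with the win-probability levels and the four trial types (Solo and the
#' three Info compositions), and shuffles the trial order.  Each
#' (menu, probability) gamble pair therefore appears exactly once per trial
#' type, and the Info types occur in equal numbers.  The social-information
#' indicator `delta` is +1 when both displayed others chose the safer gamble,
#' -1 when both chose the riskier gamble, and 0 on Solo and mixed trials.
#'
#' @param menus Menu set from [make_menu_set()] (>= `n_select` rows).
#' @param subject_id Subject identifier.
#' @param n_select Menus used per session (default 4).
#' @param probabilities Win-probability levels (default 0.40--0.90 in steps
#'   of 0.10).
#' @param seed Optional integer seed; a unique per-subject seed yields a
#'   unique trial order.
#' @return Data frame, one row per trial, with columns `subject_id`,
#'   `trial_index`, `menu_id`, `p_high`, the four payoffs, `trial_type`,
#'   `delta`.
#' @examples
#' s <- build_session(make_menu_set(), "s01", seed = 1)
#' nrow(s)            # 96
#' table(s$trial_type)
#' @export
build_session <- function(menus, subject_id, n_select = 4,
                          probabilities = seq(0.4, 0.9, by = 0.1),
                          seed = NULL) {
  if (nrow(menus) < n_select)
    stop("need at least ", n_select, " menus to build a session", call. = FALSE)
  if (any(probabilities <= 0 | probabilities >= 1))
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  with_seed(seed, {
    chosen <- menus[sort(sample.int(nrow(menus), n_select)), , drop = FALSE]
    grid <- expand.grid(
      menu_id = chosen$menu_id,
      p_high = probabilities,
      trial_type = TRIAL_TYPES,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid <- merge(grid, chosen, by = "menu_id", sort = FALSE)
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    grid$subject_id <- as.character(subject_id)
    grid$trial_index <- seq_len(nrow(grid))
    grid$delta <- delta_for_type(grid$trial_type)
    rownames(grid) <- NULL
    grid[, c("subject_id", "trial_index", "menu_id", "p_high",
             "v_high_safe", "v_low_safe", "v_high_risky", "v_low_risky",
             "trial_type", "delta")]
  })
}

#' Check the structural invariants of a session or trial table
#'
#' Verifies the safer/riskier payoff-spread ordering, the variance ordering
#' (riskier gamble strictly wider at the shared win probability), and the
#' delta coding.  Called internally by the simulators; exported because it is
#' useful on externally supplied trial tables.
#'
#' @param trials Trial data frame in the [build_session()] schema.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_trials <- function(trials) {
  need <- c("p_high", "v_high_safe", "v_low_safe", "v_high_risky",
            "v_low_risky", "trial_type", "delta")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(trials$trial_type %in% TRIAL_TYPES))
    stop("unknown trial_type values", call. = FALSE)
  if (any(trials$delta != delta_for_type(trials$trial_type)))
    stop("delta coding inconsistent with trial_type", call. = FALSE)
  if (any(trials$v_high_risky <= trials$v_high_safe) ||
      any(trials$v_low_risky >= trials$v_low_safe))
    stop("payoff spread invariant violated (riskier must be wider)", call. = FALSE)
  vs <- gamble_variance(trials$p_high, trials$v_high_safe, trials$v_low_safe)
  vr <- gamble_variance(trials$p_high, trials$v_high_risky, trials$v_low_risky)
  if (any(vr <= vs))
    stop("riskier gamble must have strictly greater payoff variance", call. = FALSE)
  invisible(TRUE)
}
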