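MODEL_NAMES <- c("solo_rp", "ocu", "ocu_free", "hybrid")

#' Model specification for the nested choice-model family
#'
#' Four nested models of safe-vs-risky choice:
#' * `solo_rp` -- power utility + softmax, no social terms (OCU fixed at 0,
#'   `w_utility` = 1);
#' * `ocu` -- adds other-conferred utility, an additive utility bonus signed
#'   by the social indicator delta (`w_utility` = 1);
#' * `ocu_free` -- pure follow/oppose heuristic on unanimous Info trials
#'   (OCU = 0, `w_follow + w_oppose = 1` there), utility-based on Solo and
#'   mixed trials;
#' * `hybrid` -- full simplex mixture `w_follow + w_oppose + w_utility = 1`
#'   of the heuristic and utility routes.
#'
#' Free-parameter counts follow the hierarchical roster: two hyperparameters
#' (mean, variance) per hierarchical parameter plus the individually
#' estimated simplex weights minus one: 4 (solo_rp), 6 (ocu), 5 (ocu_free),
#' 8 (hybrid).
#'
#' @param name One of `"solo_rp"`, `"ocu"`, `"ocu_free"`, `"hybrid"`.
#' @return A `model_spec` object.
#' @examples
#' model_spec("hybrid")$n_free
#' @export
model_spec <- function(name = MODEL_NAMES) {
  name <- match.arg(name)
  hier <- switch(name,
    solo_rp  = c("beta", "alpha"),
    ocu      = c("beta", "alpha", "ocu"),
    ocu_free = c("beta", "alpha"),
    hybrid   = c("beta", "alpha", "ocu"))
  n_weights <- switch(name, solo_rp = 0L, ocu = 0L, ocu_free = 2L, hybrid = 3L)
  # simplex constraint removes one weight degree of freedom
  n_free <- 2L * length(hier) + max(0L, n_weights - 1L)
  # per-subject free parameters (used for individual-level fit penalties)
  n_free_subject <- length(hier) + max(0L, n_weights - 1L)
  structure(list(name = name, hier_params = hier, n_weights = n_weights,
                 n_free = n_free, n_free_subject = n_free_subject),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "\n",
      " hierarchical parameters:", paste(x$hier_params, collapse = ", "), "\n",
      " simplex weights:", x$n_weights, "\n",
      " free parameters (group-level roster):", x$n_free, "\n")
  invisible(x)
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

#' Agent parameter set
#'
#' Bundles and validates the parameters of a single decision-maker: inverse
#' temperature `beta` (> 0; higher = less noisy choice), risk preference
#' `alpha` (> 0; the power-utility exponent, < 1 risk averse, 1 neutral,
#' > 1 seeking), other-conferred utility `ocu` (utility units, any sign),
#' and the mixture weights `w_follow`, `w_oppose`, `w_utility` which must
#' form a simplex.
#'
#' @param beta,alpha,ocu,w_follow,w_oppose,w_utility Scalars as above.
#' @return An `agent_parameters` object (named list).
#' @examples
#' agent_parameters(beta = 3, alpha = 0.8, ocu = 0.4,
#'                  w_follow = 0.2, w_oppose = 0.1, w_utility = 0.7)
#' @export
agent_parameters <- function(beta, alpha, ocu = 0,
                             w_follow = 0, w_oppose = 0, w_utility = 1) {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  w <- c(w_follow, w_oppose, w_utility)
  if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-10)
    stop("w_follow, w_oppose, w_utility must form a simplex (sum 1)", call. = FALSE)
  structure(list(beta = beta, alpha = alpha, ocu = ocu,
                 w_follow = w_follow, w_oppose = w_oppose, w_utility = w_utility),
            class = "agent_parameters")
}

#' @export
print.agent_parameters <- function(x, ...) {
  cat(sprintf(
    "<agent_parameters> beta=%.3g alpha=%.3g ocu=%.3g w=(%.3g, %.3g, %.3g)\n",
    x$beta, x$alpha, x$ocu, x$w_follow, x$w_oppose, x$w_utility))
  invisible(x)
}

#' Expected power utility of a two-outcome gamble
#'
#' `U = p_high * v_high^alpha + (1 - p_high) * v_low^alpha`.
#'
#' @param p_high Win probability.
#' @param v_high,v_low Payoffs (> 0).
#' @param alpha Risk-preference exponent (> 0).
#' @return Utility, vectorised over all arguments.
#' @examples
#' gamble_utility(0.6, 2.0, 1.6, 1)  # expected value, 1.84
#' @export
gamble_utility <- function(p_high, v_high, v_low, alpha) {
  if (any(v_high <= 0) || any(v_low <= 0))
    stop("payoffs must be positive", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  p_high * v_high^alpha + (1 - p_high) * v_low^alpha
}

utility_difference <- function(trials, alpha) {
  gamble_utility(trials$p_high, trials$v_high_safe, trials$v_low_safe, alpha) -
    gamble_utility(trials$p_high, trials$v_high_risky, trials$v_low_risky, alpha)
}

#' Safe-choice probability under the solo power-utility model
#'
#' Softmax (logistic) choice rule over the utility difference:
#' `P(safe) = 1 / (1 + exp(-beta * (U_safe - U_risky)))`.
#'
#' @param trials Trial table rows in the [build_session()] schema.
#' @param params An [agent_parameters()] object (or list with `beta`, `alpha`).
#' @return Vector of safe-choice probabilities, strictly inside (0, 1).
#' @export
p_safe_solo <- function(trials, params) {
  plogis(params$beta * utility_difference(trials, params$alpha))
}

#' Safe-choice probability under the other-conferred-utility model
#'
#' Adds the social bonus `delta * ocu` to the utility difference, where
#' `delta` is +1 when both observed others chose the safer gamble, -1 when
#' both chose the riskier, 0 otherwise.  Reduces to [p_safe_solo()] when
#' `ocu = 0` or `delta = 0`.
#'
#' @inheritParams p_safe_solo
#' @export
p_safe_ocu <- function(trials, params) {
  ocu <- if (is.null(params$ocu)) 0 else params$ocu
  plogis(params$beta * (utility_difference(trials, params$alpha) +
                          trials$delta * ocu))
}

#' Safe-choice probability under the hybrid mixture model
#'
#' Simplex mixture of the follow heuristic, the oppose heuristic, and the
#' OCU-based utility route:
#' on Info 'safe' trials `P = w_follow + w_utility * P_OCU`;
#' on Info 'risky' trials `P = w_oppose + w_utility * P_OCU`;
#' on Solo and Info 'mix' trials `P = P_OCU`.
#' The heuristic weights therefore bound the attainable safe-choice
#' probability on unanimous Info trials: within `[w_follow, 1 - w_oppose]`
#' on Info 'safe', `[w_oppose, 1 - w_follow]` on Info 'risky'.
#'
#' @inheritParams p_safe_solo
#' @param params Parameters with a full weight simplex.
#' @export
p_safe_hybrid <- function(trials, params) {
  w <- c(params$w_follow, params$w_oppose, params$w_utility)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-10)
    stop("weights must form a simplex", call. = FALSE)
  pocu <- p_safe_ocu(trials, params)
  ifelse(trials$trial_type == "INFO_SAFE",  params$w_follow + params$w_utility * pocu,
  ifelse(trials$trial_type == "INFO_RISKY", params$w_oppose + params$w_utility * pocu,
         pocu))
}

#' Safe-choice probability under the pure follow/oppose heuristic model
#'
#' On unanimous Info trials the choice is a mixture of following
#' (probability `w_follow`) and opposing (`1 - w_follow`) the others'
#' choice, independent of the gambles; Solo and mixed trials fall back to
#' the utility route with `ocu = 0`.
#'
#' @inheritParams p_safe_solo
#' @export
p_safe_ocu_free <- function(trials, params) {
  psolo <- p_safe_solo(trials, params)
  wf <- params$w_follow
  ifelse(trials$trial_type == "INFO_SAFE", wf,
  ifelse(trials$trial_type == "INFO_RISKY", 1 - wf, psolo))
}

#' Per-trial safe-choice probability under any model of the family
#'
#' @param model A [model_spec()] or model name.
#' @inheritParams p_safe_solo
#' @export
p_safe <- function(model, trials, params) {
  switch(as_model_spec(model)$name,
    solo_rp  = p_safe_solo(trials, params),
    ocu      = p_safe_ocu(trials, params),
    ocu_free = p_safe_ocu_free(trials, params),
    hybrid   = p_safe_hybrid(trials, params))
}

#' Normalized other-conferred utility
#'
#' Maps the OCU parameter onto the choice-probability scale,
#' `1 / (1 + exp(-beta * ocu))`, i.e. the probability shift the social bonus
#' alone produces; used when reporting and correlating recovered OCU values.
#'
#' @param beta Inverse temperature (> 0).
#' @param ocu Other-conferred utility.
#' @return Value in (0, 1); 0.5 means no social bonus.
#' @export
normalized_ocu <- function(beta, ocu) {
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  plogis(beta * ocu)
}

#' Negative log likelihood of observed choices under a model
#'
#' `-sum log Bernoulli(choice | P_safe)` with `choice = 1` coding the safer
#' gamble.  Probabilities are clamped to `[clamp, 1 - clamp]` so that
#' degenerate heuristic weights (exactly 0 or 1) with a discordant choice
#' yield a finite value.
#'
#' @param model Model name or [model_spec()].
#' @param trials Trial table.
#' @param choices 0/1 vector aligned with `trials` rows (1 = safer chosen).
#' @param params [agent_parameters()].
#' @param trial_filter Optional subset of trial types, e.g. `"SOLO"`.
#' @param clamp Probability floor (default 1e-9).
#' @return Scalar negative log likelihood (>= 0).
#' @examples
#' tr <- build_session(make_menu_set(), "s", seed = 1)
#' pars <- agent_parameters(beta = 2, alpha = 0.9)
#' neg_log_likelihood("solo_rp", tr, rbinom(96, 1, 0.5), pars)
#' @export
neg_log_likelihood <- function(model, trials, choices, params,
                               trial_filter = NULL, clamp = 1e-9) {
  if (length(choices) != nrow(trials))
    stop("choices and trials are misaligned", call. = FALSE)
  if (!is.null(trial_filter)) {
    keep <- trials$trial_type %in% trial_filter
    trials <- trials[keep, , drop = FALSE]
    choices <- choices[keep]
  }
  p <- pmin(pmax(p_safe(model, trials, params), clamp), 1 - clamp)
  -sum(ifelse(choices == 1, log(p), log1p(-p)))
}
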