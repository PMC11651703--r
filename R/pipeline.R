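#' Read / write choice datasets as CSV
#'
#' One row per trial; columns `subject_id`, `trial_index`, `menu_id`,
#' `p_high`, `v_high_safe`, `v_low_safe`, `v_high_risky`, `v_low_risky`,
#' `trial_type`, `delta`, optionally `group` and `choice` (1 = safer gamble
#' chosen).  Probabilities are decimals (0.40, not 40%).
#'
#' @param path File path.
#' @param dataset Dataset to write.
#' @return `read_choices_csv` returns the validated data frame.
#' @export
read_choices_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(d)
  if ("choice" %in% names(d) && !all(d$choice %in% 0:1))
    stop("choice column must be 0/1", call. = FALSE)
  d
}

#' @rdname read_choices_csv
#' @export
write_choices_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    sidecar <- sub("\\.csv$", "", path)
    jsonlite::write_json(truth, paste0(sidecar, "_truth.json"),
                         dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Simulate a full multi-group cohort
#'
#' Runs the task generator and cohort simulator for every group spec,
#' applies the behavioral exclusion rules with resampling, and returns one
#' combined dataset (exactly the specified number of included subjects per
#' group, each with a complete randomized session).
#'
#' @param specs Named list of [group_spec()]s (default
#'   [default_cohort_spec()]).
#' @param model Generating model (default `"hybrid"`).
#' @param seed Integer seed; per-group streams derive from it.
#' @param menus Menu set.
#' @return Choice dataset with `"truth"` attribute.
#' @export
simulate_cohort <- function(specs = default_cohort_spec(), model = "hybrid",
                            seed = 1, menus = make_menu_set()) {
  parts <- lapply(seq_along(specs), function(i) {
    simulate_until_valid(specs[[i]], model, seed = seed + 131L * i,
                         menus = menus, subject_prefix = specs[[i]]$label)
  })
  out <- do.call(rbind, lapply(parts, function(p) { attr(p, "truth") <- NULL; p }))
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, lapply(parts, attr, "truth"))
  attr(out, "n_resampled") <- sum(vapply(parts, attr, 0L, "n_resampled"))
  out
}

#' Group-comparison analysis of a fitted cohort
#'
#' The headline statistical battery on a cohort: pooled-bootstrap group
#' tests (lesion-like vs control) on the Solo-trial utility-model fit
#' (negative log likelihood) and on each hybrid mixture weight; the robust
#' correlation between Solo -LL and the follow weight across all subjects;
#' and the credible intervals of the hierarchical group-difference offsets
#' on log inverse temperature.
#'
#' @param hybrid_fit `hb_fit` of the hybrid model on the cohort.
#' @param solo_fit `hb_fit` of the solo risk-preference model.
#' @param dataset The cohort dataset.
#' @param lesion_groups Labels treated as the lesion-like set
#'   (default `c("INSULA", "DACC")`).
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @return An `cohort_analysis` list: `$group_tests` (data frame of
#'   bootstrap tests), `$follow_ll_correlation`, `$beta_differences`
#'   (credible intervals), `$subjects` (merged per-subject table).
#' @export
analyze_cohort <- function(hybrid_fit, solo_fit, dataset,
                           lesion_groups = c("INSULA", "DACC"),
                           n_iter = 10000, seed = 1) {
  med <- median_params(hybrid_fit)
  ll <- solo_fit_metric(solo_fit, dataset)
  tab <- merge(med, ll[, c("subject_id", "neg_ll_solo")], by = "subject_id")
  is_lesion <- tab$group %in% lesion_groups
  if (!any(is_lesion) || all(is_lesion))
    stop("need both lesion-like and control subjects", call. = FALSE)
  vars <- c("neg_ll_solo", "w_follow", "w_oppose", "w_utility")
  tests <- do.call(rbind, lapply(seq_along(vars), function(i) {
    v <- vars[i]
    bt <- bootstrap_group_test(list(tab[[v]][is_lesion], tab[[v]][!is_lesion]),
                               "t", n_iter = n_iter, seed = seed + i)
    data.frame(variable = v,
               mean_lesion = mean(tab[[v]][is_lesion]),
               mean_control = mean(tab[[v]][!is_lesion]),
               t = bt$observed, p = bt$p)
  }))
  rc <- robust_correlation(tab$neg_ll_solo, tab$w_follow,
                           n_iter = n_iter, seed = seed + 99L)
  bdiff <- if (!is.null(hybrid_fit$group_diff))
    group_difference_test(hybrid_fit) else NULL
  structure(list(group_tests = tests,
                 follow_ll_correlation = rc[c("r", "p", "r_pearson", "n_outliers")],
                 beta_differences = bdiff, subjects = tab),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n  pooled-bootstrap group tests (lesion-like vs control):\n")
  print(transform(x$group_tests, t = round(t, 3), p = signif(p, 3)),
        row.names = FALSE)
  cat(sprintf("  Solo -LL vs w_follow: robust r = %.3f, p = %.4g (%d outliers skipped)\n",
              x$follow_ll_correlation$r, x$follow_ll_correlation$p,
              x$follow_ll_correlation$n_outliers))
  if (!is.null(x$beta_differences)) {
    cat("  log-beta group differences:\n")
    print(x$beta_differences, row.names = FALSE)
  }
  invisible(x)
}

#' Save an analysis summary as JSON
#'
#' @param x A `cohort_analysis`, `recovery_report` or `model_recovery`.
#' @param path Output path.
#' @param seed Seed recorded alongside the results.
#' @export
write_summary_json <- function(x, path, seed = NULL) {
  out <- list(seed = seed)
  if (inherits(x, "cohort_analysis")) {
    out$group_tests <- x$group_tests
    out$follow_ll_correlation <- x$follow_ll_correlation
    out$beta_differences <- x$beta_differences
  } else if (inherits(x, "recovery_report")) {
    out$correlations <- x$correlations
    out$n_resampled <- x$n_resampled
  } else if (inherits(x, "model_recovery")) {
    out$ibic_table <- as.data.frame(x$ibic_table)
    out$confusion <- as.data.frame(x$confusion)
    out$inversion <- as.data.frame(x$inversion)
  } else out$value <- x
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
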