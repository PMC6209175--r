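#' Per-trial settling proportions
#'
#' The proportion of settled beetles that chose the focal shelter in each
#' trial. The denominator is the number of beetles that settled in either
#' shelter (not the number released): the assay design waits for every
#' individual to aggregate, but the analysis stays robust to non-settlers.
#' Trials where nothing settled carry no information and are dropped with a
#' warning.
#'
#' @param trials A validated choice-trial tibble (see [as_choice_trials()]).
#' @param focal Which shelter is focal: 1 or 2 (default 1).
#' @return A tibble: `experiment_id`, `trial_id`, `n_settled`, `proportion`.
#' @export
trial_proportions <- function(trials, focal = 1) {
  stopifnot(focal %in% c(1, 2))
  settled <- trials$shelter1_count + trials$shelter2_count
  empty <- settled == 0
  if (any(empty)) {
    warning(sprintf("excluded %d trial(s) with no settled beetles", sum(empty)))
  }
  foc <- if (focal == 1) trials$shelter1_count else trials$shelter2_count
  tibble::tibble(
    experiment_id = trials$experiment_id,
    trial_id = trials$trial_id,
    n_settled = settled,
    proportion = foc / settled
  )[!empty, ]
}

#' Percentile-bootstrap CI for a mean settling proportion
#'
#' Resamples whole trials with replacement (beetles within a trial are not
#' independent, so the trial is the resampling unit), takes the mean trial
#' proportion of each resample, and reads the confidence interval from the
#' empirical 2.5/97.5 percentiles of those resampled means.
#'
#' @param proportions Numeric vector of per-trial proportions.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `mean_proportion`, `ci_lower`, `ci_upper`,
#'   `n_trials`, `n_boot`, `seed_used`, `method` (`"percentile"`),
#'   `preferred` (see [preference_decision()]).
#' @export
#' @examples
#' bootstrap_mean_ci(c(0.6, 0.7, 0.55, 0.8), n_boot = 2000, seed = 1)
bootstrap_mean_ci <- function(proportions, n_boot = 10000, seed = 1,
                              conf = 0.95) {
  stopifnot(length(proportions) >= 1, n_boot >= 1)
  if (any(proportions < 0 | proportions > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  n <- length(proportions)
  means <- withr::with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(proportions[idx], nrow = n))
  })
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(means, c(a, 1 - a)))
  out <- tibble::tibble(
    mean_proportion = mean(proportions),
    ci_lower = ci[1], ci_upper = ci[2],
    n_trials = n, n_boot = as.integer(n_boot),
    seed_used = as.integer(seed), method = "percentile"
  )
  out$preferred <- preference_decision(out)
  out
}

#' Shelter-preference decision rule
#'
#' A shelter type is judged preferred when the mean settling proportion
#' exceeds 0.5 (the no-preference expectation) and the 95% confidence
#' interval excludes 0.5 from below.
#'
#' @param result A tibble with columns `mean_proportion`, `ci_lower`
#'   (vectorized over rows).
#' @return Logical vector.
#' @export
#' @examples
#' preference_decision(data.frame(mean_proportion = 0.59, ci_lower = 0.51))
preference_decision <- function(result) {
  result$mean_proportion > 0.5 & result$ci_lower > 0.5
}

#' Bootstrap analysis of every experiment in a choice-trial table
#'
#' Splits the table by experiment, computes per-trial proportions for the
#' focal shelter and the percentile-bootstrap CI of their mean; per-experiment
#' child seeds are derived from the root seed and the experiment label.
#'
#' @param trials A validated choice-trial tibble.
#' @param focal Focal shelter, 1 or 2.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Root integer seed.
#' @return A tibble of class `"aggmix_boot"`, one row per experiment.
#' @export
analyze_choice_experiments <- function(trials, focal = 1, n_boot = 10000,
                                       seed = 1) {
  props <- trial_proportions(trials, focal = focal)
  out <- props |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::group_modify(function(g, key) {
      bootstrap_mean_ci(g$proportion, n_boot = n_boot,
                        seed = child_seed(seed, key$experiment_id[[1]]))
    }) |>
    dplyr::ungroup()
  structure(out, class = c("aggmix_boot", class(out)),
            focal = focal, root_seed = seed)
}
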