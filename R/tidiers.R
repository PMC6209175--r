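#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a randomization result
#'
#' @param x An `aggmix_random` tibble from [randomize_aggregations()].
#' @param ... Unused.
#' @return A plain tibble, one row per aggregation.
#' @exportS3Method generics::tidy
tidy.aggmix_random <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Glance at a randomization result
#'
#' One-row summary: the category counts and fractions plus the one-sided
#' binomial meta-test of the nonrandom fraction against the type-1 baseline.
#'
#' @param x An `aggmix_random` tibble.
#' @param p0 Baseline rejection probability for the meta-test (defaults to
#'   the run's alpha).
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.aggmix_random <- function(x, p0 = NULL, ...) {
  alpha <- attr(x, "alpha")
  p0 <- p0 %||% alpha
  s <- summarize_categories(x)
  s$alpha <- alpha
  s$statistic_mode <- attr(x, "statistic")
  s$binomial_p <- nonrandom_binomial_test(s$n_nonrandom, s$n_total, p0 = p0)
  s
}

#' Tidy a choice-experiment bootstrap result
#'
#' @param x An `aggmix_boot` tibble from [analyze_choice_experiments()].
#' @param ... Unused.
#' @return A plain tibble, one row per experiment.
#' @exportS3Method generics::tidy
tidy.aggmix_boot <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Glance at a choice-experiment bootstrap result
#'
#' @param x An `aggmix_boot` tibble.
#' @param ... Unused.
#' @return A one-row tibble: experiments analysed, trials pooled, and how
#'   many experiments met the preference rule.
#' @exportS3Method generics::glance
glance.aggmix_boot <- function(x, ...) {
  tibble::tibble(
    n_experiments = nrow(x),
    n_trials_total = sum(x$n_trials),
    n_preferred = sum(x$preferred),
    focal_shelter = attr(x, "focal")
  )
}
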