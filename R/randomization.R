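#' Expected per-species counts under random settlement
#'
#' Under the multinomial null, the expected number of individuals of species
#' s in an aggregation of size n is its site-wide relative abundance times n.
#' Every species recorded at the site appears in the output, with observed
#' count zero-filled, so the expected counts sum to the aggregation size.
#'
#' @param data A validated aggregation tibble.
#' @return A tibble: `site`, `aggregation_id`, `species`, `observed`,
#'   `expected`.
#' @export
#' @examples
#' d <- as_aggregations(data.frame(
#'   site = "S1", aggregation_id = c("A1", "A1", "A2"),
#'   species = c("sp1", "sp2", "sp1"), count = c(3, 1, 1)
#' ))
#' expected_counts(d)
expected_counts <- function(data) {
  prof <- site_profile(data)
  recs <- aggregation_records(data)
  grid <- dplyr::inner_join(
    recs[, c("site", "aggregation_id", "size_n")],
    prof[, c("site", "species", "proportion")],
    by = "site", relationship = "many-to-many"
  )
  grid |>
    dplyr::left_join(data, by = c("site", "aggregation_id", "species")) |>
    dplyr::mutate(
      observed = dplyr::coalesce(.data$count, 0L),
      expected = .data$proportion * .data$size_n
    ) |>
    dplyr::select("site", "aggregation_id", "species", "observed", "expected")
}

#' Exact probability of a presence/absence pattern under multinomial sampling
#'
#' Closed-form probability that a multinomial draw of `n` individuals from
#' the given species proportions contains every species in `pattern` at least
#' once and no other species. Computed by inclusion-exclusion over the
#' subsets T of the pattern S:
#' \deqn{P = \sum_{T \subseteq S} (-1)^{|S|-|T|} \Big(\sum_{s \in T} p_s\Big)^n}
#'
#' @param pattern Character vector of species present (non-empty).
#' @param proportions Named numeric vector of species proportions (sums to 1).
#' @param n Aggregation size.
#' @return The exact pattern probability in `[0, 1]`.
#' @export
#' @examples
#' pattern_probability_exact(c("a", "b"), c(a = 0.6, b = 0.3, c = 0.1), 3)
pattern_probability_exact <- function(pattern, proportions, n) {
  pattern <- unique(as.character(pattern))
  k <- length(pattern)
  if (k == 0) stop("pattern must be non-empty", call. = FALSE)
  if (k > 25) stop("pattern too large to enumerate (> 25 species)", call. = FALSE)
  p <- proportions[pattern]
  p[is.na(p)] <- 0
  if (any(p == 0)) return(0)
  total <- 0
  for (mask in 0:(2^k - 1)) {
    inT <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
    total <- total + (-1)^(k - sum(inT)) * sum(p[inT])^n
  }
  min(max(total, 0), 1)
}

#' Expected species richness of a null draw
#'
#' The mean number of species present in a multinomial sample of size `n`:
#' \eqn{E[S] = \sum_i (1 - (1 - p_i)^n)}.
#'
#' @inheritParams pattern_probability_exact
#' @return Expected richness (a real number in `[1, length(proportions)]`).
#' @export
expected_richness <- function(proportions, n) {
  sum(1 - (1 - proportions)^n)
}

#' Monte-Carlo pattern probability for one aggregation
#'
#' Resamples `n` individuals with replacement from the site proportions
#' `n_resamples` times and reports the fraction of resamples whose
#' presence/absence pattern equals the observed pattern
#' (`statistic = "pattern"`) or whose richness equals the observed richness
#' (`statistic = "richness"`). The raw fraction is the p-value (it can be 0);
#' an add-one-corrected value `(k + 1) / (B + 1)` is reported alongside.
#'
#' @param pattern Character vector of observed species.
#' @param proportions Named numeric vector of site proportions.
#' @param n Aggregation size.
#' @param n_resamples Number of resamples (default 10000).
#' @param seed Integer seed; the draw is reproducible.
#' @param statistic `"pattern"` (default) or `"richness"`.
#' @return A list: `p_value`, `p_value_add_one`, `observed_richness`,
#'   `richness_lower_tail`, `richness_upper_tail`, `richness_draws`
#'   (integer vector of resample richness).
#' @export
pattern_probability_mc <- function(pattern, proportions, n,
                                   n_resamples = 10000, seed = 1,
                                   statistic = c("pattern", "richness")) {
  statistic <- match.arg(statistic)
  stopifnot(n_resamples >= 1, n >= 1)
  pattern <- unique(as.character(pattern))
  species <- names(proportions)
  obs_presence <- species %in% pattern
  draws <- withr::with_seed(seed,
    stats::rmultinom(n_resamples, size = n, prob = proportions))
  present <- draws > 0
  rich <- colSums(present)
  obs_rich <- length(pattern)
  hits <- if (statistic == "pattern") {
    colSums(present == obs_presence) == length(species)
  } else {
    rich == obs_rich
  }
  k <- sum(hits)
  list(
    p_value = k / n_resamples,
    p_value_add_one = (k + 1) / (n_resamples + 1),
    observed_richness = obs_rich,
    richness_lower_tail = mean(rich <= obs_rich),
    richness_upper_tail = mean(rich >= obs_rich),
    richness_draws = as.integer(rich)
  )
}

#' Classify an aggregation from its randomization results
#'
#' An aggregation is `random` when its pattern probability exceeds `alpha`.
#' Nonrandom aggregations are split by where the observed richness falls in
#' the null richness distribution: `more_species` when the upper-tail
#' fraction is at most `alpha`, `fewer_species` when the lower-tail fraction
#' is, and `other_nonrandom` when the composition deviates in species
#' identity rather than richness.
#'
#' @param p_value Pattern probability (vectorized).
#' @param richness_lower_tail Fraction of null resamples with richness at or
#'   below the observed value.
#' @param richness_upper_tail Fraction at or above the observed value.
#' @param alpha Significance level (default 0.05).
#' @return A factor with levels `random`, `more_species`, `fewer_species`,
#'   `other_nonrandom`.
#' @export
classify_aggregation <- function(p_value, richness_lower_tail,
                                 richness_upper_tail, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  cat_chr <- ifelse(p_value > alpha, "random",
             ifelse(richness_upper_tail <= alpha, "more_species",
             ifelse(richness_lower_tail <= alpha, "fewer_species",
                    "other_nonrandom")))
  factor(cat_chr, levels = c("random", "more_species", "fewer_species",
                             "other_nonrandom"))
}

#' Randomization test of aggregation composition
#'
#' The core analysis: for every aggregation of size n, resamples n
#' individuals with replacement from the abundance profile of its own site
#' and asks how probable the observed presence/absence pattern (or richness)
#' is under that null. Each aggregation gets a deterministic child seed
#' derived from the root `seed` and its (site, aggregation) label, so results
#' do not depend on processing order.
#'
#' @param data A validated aggregation tibble (lone individuals filtered).
#' @param n_resamples Resamples per aggregation (default 10000).
#' @param alpha Significance level (default 0.05).
#' @param seed Root integer seed.
#' @param statistic `"pattern"` (default) or `"richness"`; see
#'   [pattern_probability_mc()].
#' @return A tibble of class `"aggmix_random"`, one row per aggregation:
#'   size, observed and expected richness, p-values, richness tail fractions,
#'   category and the child seed used. [glance()] gives the category summary
#'   with the binomial meta-test; [autoplot()] plots it.
#' @export
#' @examples
#' prof <- gen_site_profile(c(a = 0.6, b = 0.3, c = 0.1))
#' d <- gen_null_dataset(prof, sizes = c(4, 9, 17), seed = 7)
#' randomize_aggregations(d, n_resamples = 500, seed = 7)
randomize_aggregations <- function(data, n_resamples = 10000, alpha = 0.05,
                                   seed = 1,
                                   statistic = c("pattern", "richness")) {
  statistic <- match.arg(statistic)
  stopifnot(n_resamples >= 1, alpha > 0, alpha < 1)
  recs <- aggregation_records(data)
  if (nrow(recs) == 0) stop("empty dataset", call. = FALSE)
  prof <- site_profile(data)

  rows <- purrr::pmap(recs, function(site, aggregation_id, size_n, richness,
                                     pattern) {
    p <- profile_vector(prof, site)
    sd_i <- child_seed(seed, paste(site, aggregation_id, sep = "/"))
    mc <- pattern_probability_mc(pattern, p, size_n,
                                 n_resamples = n_resamples, seed = sd_i,
                                 statistic = statistic)
    tibble::tibble(
      site = site, aggregation_id = aggregation_id, size_n = size_n,
      observed_richness = mc$observed_richness,
      expected_richness = expected_richness(p, size_n),
      p_value = mc$p_value,
      p_value_add_one = mc$p_value_add_one,
      richness_lower_tail = mc$richness_lower_tail,
      richness_upper_tail = mc$richness_upper_tail,
      seed_used = sd_i
    )
  })
  out <- dplyr::bind_rows(rows)
  out$category <- classify_aggregation(out$p_value, out$richness_lower_tail,
                                       out$richness_upper_tail, alpha)
  out$n_resamples <- as.integer(n_resamples)
  structure(out,
            class = c("aggmix_random", class(out)),
            alpha = alpha, statistic = statistic, root_seed = seed)
}

#' Summarize randomization categories
#'
#' @param results An `aggmix_random` tibble (or any tibble with a `category`
#'   column).
#' @return A one-row tibble: total, nonrandom, per-category counts and
#'   fractions. `n_nonrandom = n_more + n_fewer + n_other` always holds.
#' @export
summarize_categories <- function(results) {
  stopifnot(nrow(results) > 0)
  cat <- results$category
  n_total <- length(cat)
  n_more <- sum(cat == "more_species")
  n_fewer <- sum(cat == "fewer_species")
  n_other <- sum(cat == "other_nonrandom")
  tibble::tibble(
    n_total = n_total,
    n_nonrandom = n_more + n_fewer + n_other,
    n_more = n_more, n_fewer = n_fewer, n_other = n_other,
    frac_nonrandom = (n_more + n_fewer + n_other) / n_total,
    frac_more = n_more / n_total,
    frac_fewer = n_fewer / n_total,
    frac_other = n_other / n_total
  )
}

#' One-sided binomial meta-test for an excess of nonrandom aggregations
#'
#' Tests whether the number of aggregations flagged nonrandom exceeds what
#' type-1 error alone would produce: the one-sided tail
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Binomial}(n, p_0)}.
#'
#' @param k_nonrandom Number flagged nonrandom.
#' @param n_total Number of aggregations tested.
#' @param p0 Baseline rejection probability (default 0.05).
#' @return The one-sided p-value.
#' @export
#' @examples
#' nonrandom_binomial_test(16, 47)
nonrandom_binomial_test <- function(k_nonrandom, n_total, p0 = 0.05) {
  stopifnot(k_nonrandom >= 0, k_nonrandom <= n_total)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  stats::pbinom(k_nonrandom - 1, n_total, p0, lower.tail = FALSE)
}

#' Odds contrast between more- and fewer-species nonrandom aggregations
#'
#' Compares the odds that an aggregation is nonrandom-with-more-species
#' against the odds that it is nonrandom-with-fewer-species, among all
#' `n_total` aggregations, as a 1-df chi-square. Both the likelihood-ratio
#' form (default) and the Wald form on the log-odds difference are available;
#' the form used is labelled in the output. When a zero cell occurs, 0.5 is
#' added to every cell and the output flags it.
#'
#' @param n_more,n_fewer Counts in the two categories.
#' @param n_other Count of other-nonrandom aggregations (carried through for
#'   the record; not part of the 1-df contrast).
#' @param n_total Total aggregations tested.
#' @param form `"lrt"` (default) or `"wald"`.
#' @return A one-row tibble: `form`, `statistic`, `df`, `p_value`,
#'   `odds_more`, `odds_fewer`, `continuity_applied`.
#' @export
#' @examples
#' category_odds_contrast(8, 5, 3, 47, form = "wald")
category_odds_contrast <- function(n_more, n_fewer, n_other = NA_integer_,
                                   n_total, form = c("lrt", "wald")) {
  form <- match.arg(form)
  stopifnot(n_more >= 0, n_fewer >= 0, n_total >= n_more + n_fewer)
  k1 <- n_more; k2 <- n_fewer; n <- n_total
  continuity <- (k1 == 0 || k2 == 0 || k1 == n || k2 == n)
  if (continuity) {
    k1 <- k1 + 0.5; k2 <- k2 + 0.5; n <- n + 1
  }
  if (form == "wald") {
    est <- log(k1 / (n - k1)) - log(k2 / (n - k2))
    v <- 1 / k1 + 1 / (n - k1) + 1 / k2 + 1 / (n - k2)
    stat <- est^2 / v
  } else {
    ll <- function(k, p) {
      # binomial log-likelihood with the 0*log(0) = 0 convention
      t1 <- if (k > 0) k * log(p) else 0
      t2 <- if (k < n) (n - k) * log(1 - p) else 0
      t1 + t2
    }
    pp <- (k1 + k2) / (2 * n)
    stat <- 2 * (ll(k1, k1 / n) + ll(k2, k2 / n) - ll(k1, pp) - ll(k2, pp))
  }
  tibble::tibble(
    form = form,
    statistic = stat,
    df = 1L,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    odds_more = k1 / (n - k1),
    odds_fewer = k2 / (n - k2),
    n_other = n_other,
    continuity_applied = continuity
  )
}
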