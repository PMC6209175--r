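# Seeded generators emulating the statistical structure the analysis assumes:
# site abundance profiles, null (multinomial) and occupancy-reinforced
# aggregations, binomial choice trials and entry/exit logs. All generators
# take explicit seeds; none touch global RNG state (withr::with_seed).

#' Generate a site abundance profile
#'
#' Either passes fixed proportions through or samples a random profile from a
#' symmetric Dirichlet prior with the given concentration (drawn as
#' normalized gammas).
#'
#' @param proportions Named numeric vector of species proportions (summing
#'   to 1), or `NULL` to sample.
#' @param n_species Number of species when sampling.
#' @param concentration Dirichlet concentration when sampling (default 1).
#' @param total Nominal number of individuals behind the profile (used for
#'   the `total` column).
#' @param site Site label.
#' @param seed Integer seed (used only when sampling).
#' @return A site-profile tibble: `site`, `species`, `total`, `proportion`.
#' @export
gen_site_profile <- function(proportions = NULL, n_species = NULL,
                             concentration = 1, total = 1000,
                             site = "site1", seed = 1) {
  if (is.null(proportions)) {
    stopifnot(!is.null(n_species), n_species >= 1)
    g <- withr::with_seed(seed, stats::rgamma(n_species, shape = concentration))
    proportions <- stats::setNames(g / sum(g),
                                   sprintf("sp%02d", seq_len(n_species)))
  }
  if (length(proportions) == 0) stop("empty species list", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  tibble::tibble(
    site = site,
    species = canonicalize_species(names(proportions)),
    total = round(unname(proportions) * total),
    proportion = unname(proportions)
  ) |>
    dplyr::arrange(dplyr::desc(.data$proportion), .data$species)
}

# lognormal sizes truncated to >= 2 (re-draw), deterministic under seed
draw_sizes <- function(n, meanlog, sdlog, seed) {
  withr::with_seed(seed, {
    out <- integer(0)
    while (length(out) < n) {
      cand <- round(stats::rlnorm(n, meanlog, sdlog))
      out <- c(out, cand[cand >= 2])
    }
    out[seq_len(n)]
  })
}

#' Generate a dataset of randomly-assembled aggregations
#'
#' Each aggregation of size n is an independent multinomial draw from the
#' profile's proportions — exactly the distribution the randomization test
#' resamples from, so this is the analysis null.
#'
#' @param profile A site-profile tibble ([gen_site_profile()] or
#'   [site_profile()] output restricted to one site).
#' @param sizes Integer vector of aggregation sizes (each >= 2); or `NULL`
#'   to draw `n_aggregations` sizes from a lognormal truncated to >= 2.
#' @param n_aggregations Number of aggregations when `sizes` is `NULL`.
#' @param size_meanlog,size_sdlog Lognormal size-distribution parameters
#'   (defaults `log(10)` and 1, matching field aggregations with median
#'   around 10 and a long upper tail).
#' @param seed Integer seed.
#' @param id_prefix Prefix for aggregation labels.
#' @return A validated long aggregation tibble.
#' @export
gen_null_dataset <- function(profile, sizes = NULL, n_aggregations = NULL,
                             size_meanlog = log(10), size_sdlog = 1,
                             seed = 1, id_prefix = "agg") {
  site <- unique(profile$site)
  stopifnot(length(site) == 1)
  p <- stats::setNames(profile$proportion, profile$species)
  if (is.null(sizes)) {
    stopifnot(!is.null(n_aggregations))
    sizes <- draw_sizes(n_aggregations, size_meanlog, size_sdlog,
                        child_seed(seed, paste0(site, "/sizes")))
  }
  stopifnot(all(sizes >= 2))
  counts <- withr::with_seed(child_seed(seed, paste0(site, "/draws")),
    vapply(sizes, function(n) stats::rmultinom(1, n, p)[, 1],
           numeric(length(p))))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(p))
  long <- tibble::tibble(
    site = site,
    aggregation_id = rep(sprintf("%s%03d", id_prefix, seq_along(sizes)),
                         each = length(p)),
    species = rep(names(p), times = length(sizes)),
    count = as.integer(counts)
  )
  as_aggregations(long[long$count > 0, ])
}

#' Generate aggregations under occupancy-reinforced settlement
#'
#' A minimal urn scheme giving the test suite a one-parameter alternative to
#' the null: individuals (species drawn independently from the profile)
#' arrive one at a time and join shelter j with probability proportional to
#' `1 + theta * w_j`, where `w_j` counts current occupants of shelter j with
#' heterospecific occupants weighted by `heterospecific_weight`. At
#' `theta = 0` shelter choice is uniform and the scheme collapses exactly to
#' the multinomial null; `heterospecific_weight = 1` is species-blind
#' reinforcement, `heterospecific_weight = 0` conspecific-only. Shelters
#' ending with at least two occupants become aggregations.
#'
#' @param profile A one-site profile tibble.
#' @param n_individuals Number of arriving individuals.
#' @param theta Reinforcement strength (>= 0; 0 = null).
#' @param heterospecific_weight Relative pull of heterospecific occupants
#'   (default 1).
#' @param n_shelters Number of available shelters.
#' @param seed Integer seed.
#' @param id_prefix Prefix for aggregation labels.
#' @return A validated long aggregation tibble (shelters with < 2 occupants
#'   are dropped, as lone individuals are in the field protocol).
#' @export
gen_attraction_dataset <- function(profile, n_individuals, theta = 0,
                                   heterospecific_weight = 1, n_shelters = 10,
                                   seed = 1, id_prefix = "shl") {
  stopifnot(theta >= 0, heterospecific_weight >= 0, n_shelters >= 1,
            n_individuals >= 1)
  site <- unique(profile$site)
  stopifnot(length(site) == 1)
  p <- stats::setNames(profile$proportion, profile$species)
  k <- length(p)
  occ <- matrix(0L, nrow = k, ncol = n_shelters,
                dimnames = list(names(p), NULL))
  withr::with_seed(child_seed(seed, paste0(site, "/urn")), {
    spp <- sample.int(k, n_individuals, replace = TRUE, prob = p)
    for (i in seq_len(n_individuals)) {
      s <- spp[i]
      w <- occ[s, ] + heterospecific_weight * (colSums(occ) - occ[s, ])
      prob <- 1 + theta * w
      j <- sample.int(n_shelters, 1, prob = prob)
      occ[s, j] <- occ[s, j] + 1L
    }
  })
  keep <- which(colSums(occ) >= 2)
  if (length(keep) == 0) stop("no shelter reached 2 occupants", call. = FALSE)
  long <- tibble::tibble(
    site = site,
    aggregation_id = rep(sprintf("%s%03d", id_prefix, keep), each = k),
    species = rep(names(p), times = length(keep)),
    count = as.integer(occ[, keep])
  )
  as_aggregations(long[long$count > 0, ])
}

#' Generate two-shelter choice trials with a known preference
#'
#' Per trial, the focal-shelter count is Binomial(`beetles_per_trial`,
#' `p_true`) and the remainder settles in the other shelter.
#'
#' @param p_true True probability of settling in the focal (shelter 1).
#' @param beetles_per_trial Beetles released per trial (default 25, the
#'   standard assay size).
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param experiment_id Experiment label.
#' @param shelter_labels Length-2 character vector of shelter descriptions.
#' @return A validated choice-trial tibble.
#' @export
gen_choice_trials <- function(p_true, beetles_per_trial = 25, n_trials = 20,
                              seed = 1, experiment_id = "exp1",
                              shelter_labels = c("occupied", "empty")) {
  stopifnot(p_true >= 0, p_true <= 1, n_trials >= 1)
  foc <- withr::with_seed(seed,
    stats::rbinom(n_trials, beetles_per_trial, p_true))
  as_choice_trials(tibble::tibble(
    experiment_id = experiment_id,
    trial_id = sprintf("t%03d", seq_len(n_trials)),
    shelter1_label = shelter_labels[1],
    shelter1_count = foc,
    shelter2_label = shelter_labels[2],
    shelter2_count = beetles_per_trial - foc,
    n_released = beetles_per_trial
  ))
}

#' Generate a shelter entry/exit event log
#'
#' Produces a random interleaving of permanent entries (reaching the
#' specified final counts) plus transient visits (an entry followed by a
#' later exit), so replaying the log through [build_occupancy_curves()]
#' always ends at `final_counts` and never drives occupancy negative.
#'
#' @param final_counts Named integer vector: final occupancy per shelter.
#' @param churn Expected number of transient visits per shelter (Poisson;
#'   default 0).
#' @param t_max Recording length in minutes (default 300).
#' @param seed Integer seed.
#' @return A validated event-log tibble.
#' @export
gen_event_log <- function(final_counts, churn = 0, t_max = 300, seed = 1) {
  stopifnot(churn >= 0, all(final_counts >= 0))
  shelters <- names(final_counts) %||% sprintf("S%d", seq_along(final_counts))
  rows <- withr::with_seed(seed, {
    purrr::map2(shelters, as.integer(final_counts), function(sh, fc) {
      entries <- tibble::tibble(time_min = stats::runif(fc, 0, t_max),
                                shelter_id = sh, delta = 1L)
      n_visits <- stats::rpois(1, churn)
      visits <- purrr::map(seq_len(n_visits), function(i) {
        ts <- sort(stats::runif(2, 0, t_max))
        tibble::tibble(time_min = ts, shelter_id = sh, delta = c(1L, -1L))
      })
      dplyr::bind_rows(entries, visits)
    })
  })
  log <- dplyr::bind_rows(rows)
  # stable order: time, then entries before exits at identical times
  log <- log[order(log$time_min, -log$delta), ]
  as_event_log(log)
}
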