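#' Summarize aggregation sizes
#'
#' @param data A validated aggregation tibble (lone individuals filtered).
#' @return A one-row tibble: `n_aggregations`, `n_individuals`, `mean_size`,
#'   `median_size` (midpoint convention for even counts), `min_size`,
#'   `max_size`.
#' @export
size_summary <- function(data) {
  recs <- aggregation_records(data)
  if (nrow(recs) == 0) stop("empty dataset", call. = FALSE)
  tibble::tibble(
    n_aggregations = nrow(recs),
    n_individuals = sum(recs$size_n),
    mean_size = mean(recs$size_n),
    median_size = stats::median(recs$size_n),
    min_size = min(recs$size_n),
    max_size = max(recs$size_n)
  )
}

#' Fraction of aggregations holding at least `min_species` species
#'
#' @param data A validated aggregation tibble.
#' @param min_species Richness threshold (default 2, i.e. multispecies).
#' @return A one-row tibble: `min_species`, `n_total` (the denominator,
#'   exposed explicitly), `n_meeting`, `fraction`.
#' @export
multispecies_fraction <- function(data, min_species = 2) {
  stopifnot(min_species >= 2)
  recs <- aggregation_records(data)
  n_meeting <- sum(recs$richness >= min_species)
  tibble::tibble(
    min_species = as.integer(min_species),
    n_total = nrow(recs),
    n_meeting = n_meeting,
    fraction = if (nrow(recs) > 0) n_meeting / nrow(recs) else NA_real_
  )
}

#' Species participation in single- vs multispecies aggregations
#'
#' For each species, counts the aggregations it occurs in and splits them by
#' aggregation type; the two percentages sum to 100 for every species.
#'
#' @param data A validated aggregation tibble.
#' @return A tibble: `species`, `n_single`, `n_multi`, `pct_single`,
#'   `pct_multi`.
#' @export
species_participation <- function(data) {
  recs <- aggregation_records(data)
  data |>
    dplyr::distinct(.data$site, .data$aggregation_id, .data$species) |>
    dplyr::left_join(recs, by = c("site", "aggregation_id")) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_single = sum(.data$richness == 1),
      n_multi = sum(.data$richness >= 2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_single = 100 * .data$n_single / (.data$n_single + .data$n_multi),
      pct_multi = 100 * .data$n_multi / (.data$n_single + .data$n_multi)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_single + .data$n_multi), .data$species)
}

#' Per-site composition and multispecies prevalence
#'
#' @param data A validated aggregation tibble.
#' @return A tibble with one row per site: `site`, `n_aggregations`,
#'   `n_individuals`, `n_species`, `n_multi`, `pct_multispecies`.
#' @export
composition_by_site <- function(data) {
  recs <- aggregation_records(data)
  recs |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      n_aggregations = dplyr::n(),
      n_individuals = sum(.data$size_n),
      n_multi = sum(.data$richness >= 2),
      pct_multispecies = 100 * mean(.data$richness >= 2),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      data |>
        dplyr::group_by(.data$site) |>
        dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                         .groups = "drop"),
      by = "site"
    ) |>
    dplyr::relocate("n_species", .after = "n_individuals")
}
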