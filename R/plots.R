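#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a randomization result
#'
#' Bar chart of aggregation categories per site.
#'
#' @param object An `aggmix_random` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aggmix_random <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$site, fill = .data$category)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = "site", y = "aggregations",
                  fill = "classification",
                  title = "Randomization classification of aggregations") +
    ggplot2::theme_minimal()
}

#' Plot choice-experiment bootstrap intervals
#'
#' Mean settling proportion per experiment with its percentile-bootstrap CI;
#' the dashed line marks the no-preference expectation of 0.5.
#'
#' @param object An `aggmix_boot` tibble (or any tibble with
#'   `experiment_id`, `mean_proportion`, `ci_lower`, `ci_upper`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aggmix_boot <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$experiment_id,
                               y = .data$mean_proportion)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "experiment", y = "mean settling proportion",
                  title = "Shelter-choice experiments") +
    ggplot2::theme_minimal()
}

#' Plot aggregation sizes ordered smallest to largest
#'
#' @param data A validated aggregation tibble.
#' @return A ggplot.
#' @export
plot_aggregation_sizes <- function(data) {
  recs <- aggregation_records(data) |>
    dplyr::arrange(.data$size_n) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(recs, ggplot2::aes(x = .data$rank, y = .data$size_n)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$site)) +
    ggplot2::labs(x = "aggregation (ordered by size)", y = "individuals",
                  title = "Aggregation size distribution") +
    ggplot2::theme_minimal()
}

#' Plot per-shelter occupancy curves
#'
#' Step plot of shelter occupancy over time reconstructed from an event log.
#'
#' @param curves Output of [build_occupancy_curves()].
#' @return A ggplot.
#' @export
plot_occupancy <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_min,
                                       y = .data$occupancy,
                                       colour = .data$shelter_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "minutes from recording start", y = "occupancy",
                  colour = "shelter",
                  title = "Settlement dynamics") +
    ggplot2::theme_minimal()
}
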