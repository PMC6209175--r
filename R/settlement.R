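#' Per-shelter occupancy curves from an event log
#'
#' Converts a validated entry/exit log into right-continuous step functions
#' of shelter occupancy: one breakpoint per event, occupancy changing by
#' plus or minus one. Simultaneous events are applied in file order.
#'
#' @param events A validated event-log tibble (see [as_event_log()]).
#' @return A tibble: `shelter_id`, `time_min`, `occupancy`, ordered by
#'   shelter then time.
#' @export
#' @examples
#' log <- as_event_log(data.frame(
#'   time_min = c(10, 12, 30), shelter_id = "S1", delta = c(1, 1, -1)
#' ))
#' build_occupancy_curves(log)
build_occupancy_curves <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(shelter_id = character(0), time_min = numeric(0),
                          occupancy = integer(0)))
  }
  events |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$shelter_id) |>
    dplyr::arrange(.data$.row, .by_group = TRUE) |>
    dplyr::mutate(occupancy = cumsum(.data$delta)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$shelter_id, .data$.row) |>
    dplyr::select("shelter_id", "time_min", "occupancy")
}

#' Final occupancy per shelter
#'
#' @param curves Output of [build_occupancy_curves()].
#' @return A tibble: `shelter_id`, `final_occupancy`.
#' @export
final_occupancy <- function(curves) {
  curves |>
    dplyr::group_by(.data$shelter_id) |>
    dplyr::summarise(final_occupancy = dplyr::last(.data$occupancy),
                     .groups = "drop")
}

#' Settlement completion time
#'
#' The earliest time after which the summed occupancy over all shelters
#' equals `n_total` and no further events occur — the moment the aggregation
#' is complete. If beetles later leave and re-settle, the completion time is
#' the final (re-)completion. Returns `NA` when the group never fully
#' settles.
#'
#' @param events A validated event-log tibble.
#' @param n_total Total number of individuals in the arena.
#' @return Completion time in minutes, or `NA_real_`.
#' @export
settlement_completion_time <- function(events, n_total) {
  stopifnot(n_total >= 1)
  if (nrow(events) == 0) return(NA_real_)
  total <- cumsum(events$delta)
  if (total[length(total)] != n_total) return(NA_real_)
  # last time the running total moved away from n_total, then came back
  below <- which(total != n_total)
  idx <- if (length(below) == 0) which(total == n_total)[1] else max(below) + 1
  events$time_min[idx]
}
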