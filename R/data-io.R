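#' Validate an in-memory aggregation table
#'
#' An aggregation dataset is a long-format table with one row per
#' (aggregation, species) pair: columns `site`, `aggregation_id`, `species`,
#' `count`. Validation canonicalizes species names (see
#' [canonicalize_species()]), drops explicit zero-count rows (wide-to-long
#' exports often carry them), and checks the structural invariants: counts are
#' non-negative integers and no (site, aggregation, species) pair appears
#' twice.
#'
#' @param data A data frame with columns `site`, `aggregation_id`, `species`,
#'   `count`.
#' @return A validated tibble with the same columns, species canonicalized,
#'   zero-count rows removed.
#' @export
#' @examples
#' as_aggregations(data.frame(
#'   site = "S1", aggregation_id = "A1",
#'   species = c("sp1", "sp2"), count = c(3, 2)
#' ))
as_aggregations <- function(data) {
  abort_cols(data, c("site", "aggregation_id", "species", "count"),
             "aggregation table")
  data <- tibble::as_tibble(data)
  data$site <- as.character(data$site)
  data$aggregation_id <- as.character(data$aggregation_id)
  data$species <- canonicalize_species(data$species)

  bad_name <- which(data$species == "")
  if (length(bad_name) > 0) {
    stop(sprintf("empty species name at row(s): %s",
                 paste(utils::head(bad_name, 5), collapse = ", ")),
         call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(data$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad) > 0) {
    stop(sprintf("invalid count (negative, missing or non-integer) at row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  data$count <- as.integer(round(cnt))

  key <- paste(data$site, data$aggregation_id, data$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate (site, aggregation, species) row(s): %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  dplyr::filter(data, .data$count > 0)
}

#' Read an aggregation dataset from CSV
#'
#' Expects columns `site`, `aggregation_id`, `species`, `count` (UTF-8,
#' header row, comma-separated) and returns the validated long tibble
#' produced by [as_aggregations()].
#'
#' @param path Path to a CSV file.
#' @return A validated aggregation tibble.
#' @export
read_aggregations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_aggregations(raw)
}

#' Per-aggregation summaries
#'
#' Collapses a long aggregation table to one row per aggregation with its
#' total size (`size_n`), species richness, and the set of species present
#' (`pattern`, a list-column of character vectors).
#'
#' @param data A validated aggregation tibble.
#' @return A tibble with columns `site`, `aggregation_id`, `size_n`,
#'   `richness`, `pattern`.
#' @export
aggregation_records <- function(data) {
  data |>
    dplyr::group_by(.data$site, .data$aggregation_id) |>
    dplyr::summarise(
      size_n = sum(.data$count),
      richness = dplyr::n_distinct(.data$species),
      pattern = list(sort(unique(.data$species))),
      .groups = "drop"
    )
}

#' Remove lone individuals from a dataset
#'
#' Aggregations by definition hold at least two individuals; stray singletons
#' picked up during collection are removed explicitly rather than silently.
#' The removed records are attached as the `"removed"` attribute (a tibble of
#' site, aggregation_id and size) and also reported with a message.
#'
#' @param data A validated aggregation tibble.
#' @param quiet Suppress the removal message.
#' @return The filtered tibble; `attr(, "removed")` lists removed records.
#' @export
filter_lone_individuals <- function(data, quiet = FALSE) {
  recs <- aggregation_records(data)
  lone <- dplyr::filter(recs, .data$size_n < 2)
  keep <- dplyr::anti_join(data, lone[, c("site", "aggregation_id")],
                           by = c("site", "aggregation_id"))
  if (!quiet && nrow(lone) > 0) {
    message(sprintf("removed %d lone individual(s)", nrow(lone)))
  }
  attr(keep, "removed") <- lone[, c("site", "aggregation_id", "size_n")]
  keep
}

#' Site abundance profiles
#'
#' Sums individuals of each species over all aggregations collected at a site
#' and normalizes to relative proportions — the sampling weights of the
#' randomization null. Totals include every aggregation at the site (the
#' focal aggregation is not left out).
#'
#' @param data A validated aggregation tibble.
#' @param site Optional single site label; default profiles every site.
#' @return A tibble with columns `site`, `species`, `total`, `proportion`;
#'   proportions sum to 1 within each site.
#' @export
site_profile <- function(data, site = NULL) {
  if (!is.null(site)) {
    site <- as.character(site)
    if (!site %in% data$site) stop("unknown site: ", site, call. = FALSE)
    data <- dplyr::filter(data, .data$site == !!site)
  }
  data |>
    dplyr::group_by(.data$site, .data$species) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(proportion = .data$total / sum(.data$total)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$site, dplyr::desc(.data$total), .data$species)
}

# named proportion vector for one site
profile_vector <- function(profile, site) {
  p <- dplyr::filter(profile, .data$site == !!site)
  if (nrow(p) == 0) stop("unknown site: ", site, call. = FALSE)
  stats::setNames(p$proportion, p$species)
}

#' Validate / read two-shelter choice trials
#'
#' A choice-trial table has one row per trial: `experiment_id`, `trial_id`,
#' `shelter1_label`, `shelter1_count`, `shelter2_label`, `shelter2_count`,
#' `n_released`. Counts must be non-negative and sum to at most the number of
#' beetles released in the trial.
#'
#' @param data A data frame with the columns above.
#' @return A validated tibble.
#' @export
as_choice_trials <- function(data) {
  req <- c("experiment_id", "trial_id", "shelter1_label", "shelter1_count",
           "shelter2_label", "shelter2_count", "n_released")
  abort_cols(data, req, "choice-trial table")
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop("choice-trial table has no trials", call. = FALSE)
  for (col in c("shelter1_count", "shelter2_count", "n_released")) {
    v <- suppressWarnings(as.numeric(data[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop(sprintf("invalid %s at row(s): %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    data[[col]] <- as.integer(round(v))
  }
  over <- which(data$shelter1_count + data$shelter2_count > data$n_released)
  if (length(over) > 0) {
    stop(sprintf("settled counts exceed n_released at row(s): %s",
                 paste(utils::head(over, 5), collapse = ", ")), call. = FALSE)
  }
  data
}

#' @rdname as_choice_trials
#' @param path Path to a CSV file.
#' @export
read_choice_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_choice_trials(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Validate / read a shelter entry/exit event log
#'
#' An event log records, in minutes from the start of the recording, every
#' time an individual entered (`delta = +1`) or exited (`delta = -1`) a
#' shelter. Times must be non-decreasing and the running occupancy of each
#' shelter can never go negative.
#'
#' @param data A data frame with columns `time_min`, `shelter_id`, `delta`.
#' @return A validated tibble ordered as supplied.
#' @export
as_event_log <- function(data) {
  abort_cols(data, c("time_min", "shelter_id", "delta"), "event log")
  data <- tibble::as_tibble(data)
  data$time_min <- as.numeric(data$time_min)
  data$shelter_id <- as.character(data$shelter_id)
  data$delta <- as.integer(data$delta)
  if (nrow(data) == 0) return(data)
  if (any(!data$delta %in% c(-1L, 1L))) {
    stop("delta must be +1 (entry) or -1 (exit)", call. = FALSE)
  }
  if (is.unsorted(data$time_min)) {
    stop("event times must be non-decreasing", call. = FALSE)
  }
  # simultaneous events are applied in file order (stable)
  for (sh in unique(data$shelter_id)) {
    occ <- cumsum(data$delta[data$shelter_id == sh])
    if (any(occ < 0)) {
      row <- which(data$shelter_id == sh)[which(occ < 0)[1]]
      stop(sprintf("exit before entry: occupancy of shelter '%s' goes negative at row %d",
                   sh, row), call. = FALSE)
    }
  }
  data
}

#' @rdname as_event_log
#' @param path Path to a CSV file.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_event_log(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}
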