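#' Aggregation-by-species abundance matrix
#'
#' One row per aggregation, one column per species in the dataset's species
#' universe, zero-filled. Row sums equal aggregation sizes; column sums equal
#' pooled species totals.
#'
#' @param data A validated aggregation tibble.
#' @return A wide tibble: `site`, `aggregation_id`, then one integer column
#'   per species.
#' @export
abundance_matrix <- function(data) {
  species <- sort(unique(data$species))
  data |>
    tidyr::pivot_wider(
      id_cols = c("site", "aggregation_id"),
      names_from = "species", values_from = "count",
      values_fill = 0L, names_sort = TRUE
    ) |>
    dplyr::arrange(.data$site, .data$aggregation_id) |>
    dplyr::select("site", "aggregation_id", dplyr::all_of(species))
}

fisher_z_ci <- function(r, n_units, conf = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n_units - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' Reconstructs the interval implied by a coefficient and a unit count:
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{1-\alpha/2} / \sqrt{n_{units} - 3})}.
#' Useful for checking published intervals when only r and n are printed.
#'
#' @param r Correlation coefficient.
#' @param n_units Number of sampling units the coefficient was computed over.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `r`, `n_units`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' correlation_ci(-0.097, 59)
correlation_ci <- function(r, n_units, conf = 0.95) {
  stopifnot(abs(r) < 1, n_units > 3)
  ci <- fisher_z_ci(r, n_units, conf)
  tibble::tibble(r = r, n_units = as.integer(n_units),
                 ci_lower = ci[1], ci_upper = ci[2])
}

#' Pearson correlation between two species with a Fisher-z interval
#'
#' The coefficient is computed over per-aggregation abundances pooled across
#' sites. The confidence interval uses the Fisher z transform with standard
#' error \eqn{1/\sqrt{n_{units} - 3}}; `n_units` is the number of
#' aggregations the coefficient is computed over, and may be supplied
#' explicitly when reconstructing an interval from a published coefficient.
#' The two-sided p-value uses the t transform with `n_units - 2` df.
#'
#' @param data A validated aggregation tibble, or a wide matrix from
#'   [abundance_matrix()].
#' @param species_a,species_b Species names.
#' @param n_units Number of aggregation units; default the number of rows.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `species_a`, `species_b`, `method`,
#'   `coefficient`, `ci_lower`, `ci_upper`, `p_value`, `n_units`.
#' @export
pearson_with_ci <- function(data, species_a, species_b, n_units = NULL,
                            conf = 0.95) {
  wide <- if (all(c("species", "count") %in% names(data)))
    abundance_matrix(data) else data
  species_a <- canonicalize_species(species_a)
  species_b <- canonicalize_species(species_b)
  abort_cols(wide, c(species_a, species_b), "abundance matrix")
  x <- wide[[species_a]]; y <- wide[[species_b]]
  if (is.null(n_units)) n_units <- length(x)
  if (n_units < 4) stop("need at least 4 aggregation units", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance species column: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  degenerate <- abs(r) >= 1 - 1e-12
  ci <- if (degenerate) c(r, r) else fisher_z_ci(r, n_units, conf)
  tstat <- r * sqrt((n_units - 2) / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(
    species_a = species_a, species_b = species_b, method = "pearson",
    coefficient = r, ci_lower = ci[1], ci_upper = ci[2],
    p_value = 2 * stats::pt(-abs(tstat), df = n_units - 2),
    n_units = as.integer(n_units),
    degenerate = degenerate
  )
}

#' Spearman rank correlation between two species
#'
#' Rank correlation over per-aggregation abundances with midrank ties
#' (count data guarantee ties); two-sided p-value from the t approximation.
#'
#' @inheritParams pearson_with_ci
#' @return A one-row tibble matching [pearson_with_ci()]'s columns (no CI).
#' @export
spearman_rho <- function(data, species_a, species_b) {
  wide <- if (all(c("species", "count") %in% names(data)))
    abundance_matrix(data) else data
  species_a <- canonicalize_species(species_a)
  species_b <- canonicalize_species(species_b)
  abort_cols(wide, c(species_a, species_b), "abundance matrix")
  x <- wide[[species_a]]; y <- wide[[species_b]]
  n <- length(x)
  if (n < 4) stop("need at least 4 aggregation units", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("all-tied species column: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  tibble::tibble(
    species_a = species_a, species_b = species_b, method = "spearman",
    coefficient = rho, ci_lower = NA_real_, ci_upper = NA_real_,
    p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
    n_units = as.integer(n),
    degenerate = abs(rho) >= 1 - 1e-12
  )
}

#' Pairwise co-occurrence screen by abundance group
#'
#' Runs Pearson correlations (with Fisher-z intervals) for every pair within
#' the abundant group and Spearman rank correlations for every pair within
#' the rare group — the abundance-stratified design of the field analysis,
#' where the three most abundant species were tested parametrically and the
#' five rarest nonparametrically. Groups may be given explicitly or derived
#' from a pooled-abundance threshold. No multiple-testing correction is
#' applied.
#'
#' @param data A validated aggregation tibble.
#' @param abundant,rare Character vectors of species names; if both `NULL`,
#'   species with pooled abundance `>= split_threshold` are abundant.
#' @param split_threshold Pooled-count threshold used when groups are not
#'   given.
#' @return A tibble of correlation rows (see [pearson_with_ci()]); groups of
#'   size < 2 contribute no rows.
#' @export
pairwise_screen <- function(data, abundant = NULL, rare = NULL,
                            split_threshold = NULL) {
  wide <- abundance_matrix(data)
  totals <- data |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  if (is.null(abundant) && is.null(rare)) {
    if (is.null(split_threshold)) {
      stop("supply species groups or a split_threshold", call. = FALSE)
    }
    abundant <- totals$species[totals$total >= split_threshold]
    rare <- totals$species[totals$total < split_threshold]
  }
  abundant <- canonicalize_species(abundant %||% character(0))
  rare <- canonicalize_species(rare %||% character(0))

  pairs_of <- function(group) {
    if (length(group) < 2) return(NULL)
    utils::combn(sort(group), 2, simplify = FALSE)
  }
  res_a <- purrr::map(pairs_of(abundant),
                      ~ pearson_with_ci(wide, .x[1], .x[2]))
  res_r <- purrr::map(pairs_of(rare),
                      ~ spearman_rho(wide, .x[1], .x[2]))
  out <- dplyr::bind_rows(c(res_a, res_r))
  if (nrow(out) == 0) return(out)
  dplyr::left_join(out,
                   dplyr::rename(totals, species_a = "species",
                                 abundance_a = "total"),
                   by = "species_a")
}
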