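test_that("site profiles pass through or sample deterministically", {
  fixed <- gen_site_profile(c(a = 0.7, b = 0.2, c = 0.1), site = "x")
  expect_equal(sum(fixed$proportion), 1)
  expect_equal(fixed$proportion[fixed$species == "a"], 0.7)

  one <- gen_site_profile(c(solo = 1), site = "x")
  expect_equal(one$proportion, 1)

  s1 <- gen_site_profile(n_species = 5, seed = 3)
  s2 <- gen_site_profile(n_species = 5, seed = 3)
  expect_identical(s1, s2)
  expect_equal(sum(s1$proportion), 1, tolerance = 1e-12)
  expect_error(gen_site_profile(numeric(0)), "empty|sum")
})

test_that("null datasets are multinomial draws from the profile", {
  single <- gen_site_profile(c(only = 1), site = "x")
  d1 <- gen_null_dataset(single, n_aggregations = 10, seed = 1)
  expect_true(all(aggregation_records(d1)$richness == 1))

  # multinomial moments: mean per-species counts at n = 10
  prof <- gen_site_profile(c(a = 0.6, b = 0.3, c = 0.1), site = "x")
  d <- gen_null_dataset(prof, sizes = rep(10L, 10000), seed = 2)
  means <- d |>
    dplyr::group_by(species) |>
    dplyr::summarise(total = sum(count)) |>
    dplyr::mutate(mean = total / 10000)
  for (sp in c("a", "b", "c")) {
    p <- c(a = 0.6, b = 0.3, c = 0.1)[[sp]]
    se <- sqrt(10 * p * (1 - p) / 10000)
    expect_lt(abs(means$mean[means$species == sp] - 10 * p), 4 * se)
  }

  # pattern frequencies match the exact inclusion-exclusion oracle
  d3 <- gen_null_dataset(prof, sizes = rep(3L, 8000), seed = 5)
  recs <- aggregation_records(d3)
  frac <- mean(vapply(recs$pattern,
                      function(s) identical(sort(s), c("a", "b")),
                      logical(1)))
  se <- sqrt(0.486 * 0.514 / 8000)
  expect_lt(abs(frac - 0.486), 4 * se)

  expect_identical(gen_null_dataset(prof, n_aggregations = 5, seed = 9),
                   gen_null_dataset(prof, n_aggregations = 5, seed = 9))
  expect_true(all(aggregation_records(
    gen_null_dataset(prof, n_aggregations = 50, seed = 3)
  )$size_n >= 2))
})

test_that("reinforced settlement clusters occupancy and nulls out at theta zero", {
  prof <- gen_site_profile(c(a = 0.5, b = 0.3, c = 0.2), site = "x")
  # theta very large, 2 shelters: one shelter captures nearly everything
  dstrong <- gen_attraction_dataset(prof, n_individuals = 200, theta = 1000,
                                    n_shelters = 2, seed = 3)
  sizes <- aggregation_records(dstrong)$size_n
  expect_gt(max(sizes) / sum(sizes), 0.9)

  expect_identical(
    gen_attraction_dataset(prof, 100, theta = 2, n_shelters = 6, seed = 4),
    gen_attraction_dataset(prof, 100, theta = 2, n_shelters = 6, seed = 4)
  )

  # theta = 0: pooled species totals behave as multinomial draws
  pvals <- vapply(1:60, function(seed) {
    d <- gen_attraction_dataset(prof, 150, theta = 0, n_shelters = 5,
                                seed = seed)
    tot <- d |> dplyr::group_by(species) |> dplyr::summarise(t = sum(count))
    full <- setNames(rep(0, 3), c("a", "b", "c"))
    full[tot$species] <- tot$t
    suppressWarnings(stats::chisq.test(full, p = c(0.5, 0.3, 0.2))$p.value)
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.15)
})

test_that("choice-trial generation hits its binomial moments", {
  sure <- gen_choice_trials(1, n_trials = 5, seed = 1)
  expect_true(all(sure$shelter1_count == 25))

  tr <- gen_choice_trials(0.5, beetles_per_trial = 25, n_trials = 10000,
                          seed = 2)
  m <- mean(tr$shelter1_count / 25)
  se <- sqrt(0.5 * 0.5 / 25 / 10000)
  expect_lt(abs(m - 0.5), 4 * se)
  expect_identical(gen_choice_trials(0.4, n_trials = 8, seed = 3),
                   gen_choice_trials(0.4, n_trials = 8, seed = 3))
})

test_that("the synthetic survey stand-in matches the published marginals", {
  d <- synthetic_field_survey(seed = 1)
  by_site <- composition_by_site(d)
  expect_equal(by_site$n_aggregations[match(c("site2", "site3", "site6",
                                              "site7"), by_site$site)],
               c(16L, 10L, 12L, 9L))
  expect_equal(by_site$n_individuals[match(c("site2", "site3", "site6",
                                             "site7"), by_site$site)],
               c(182L, 139L, 244L, 504L))
  expect_equal(nrow(aggregation_records(d)), 47)
  expect_true(all(aggregation_records(d)$size_n >= 2))
  # dominant species match the published site profiles to a few percent
  prof <- site_profile(d)
  dom <- prof |> dplyr::group_by(site) |> dplyr::slice_max(proportion, n = 1)
  expect_equal(dom$species[dom$site == "site2"], "b. hirsutus")
  expect_equal(dom$species[dom$site == "site3"], "b. mexicanus")
  expect_true(all(dom$species[dom$site %in% c("site6", "site7")] ==
                    "b. elongatulus"))
  expect_identical(synthetic_field_survey(seed = 2),
                   synthetic_field_survey(seed = 2))
})

test_that("the null pipeline's empirical flag rate is stable and reproducible", {
  # The pattern statistic is not uniform under the null, so the empirical
  # baseline (not 0.05) is what must be reproducible.
  run_baseline <- function(root) {
    fracs <- vapply(1:50, function(i) {
      prof <- gen_site_profile(c(a = 0.5, b = 0.3, c = 0.15, d = 0.05),
                               site = "s")
      d <- gen_null_dataset(prof, n_aggregations = 10,
                            seed = child_seed(root, paste0("rep", i)))
      r <- randomize_aggregations(d, n_resamples = 400, seed = root)
      summarize_categories(r)$frac_nonrandom
    }, numeric(1))
    mean(fracs)
  }
  b1 <- run_baseline(100)
  expect_identical(b1, run_baseline(100))
  expect_gt(b1, 0)
  expect_lt(b1, 0.3)
})
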