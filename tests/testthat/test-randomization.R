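test_that("expected counts are site proportions scaled by aggregation size", {
  d <- as_aggregations(data.frame(
    site = "s1",
    aggregation_id = rep(c("a1", "a2"), times = c(3, 1)),
    species = c("sp1", "sp2", "sp3", "sp1"),
    count = c(10, 5, 4, 1)
  ))
  # site totals: sp1 11, sp2 5, sp3 4 -> proportions 0.55, 0.25, 0.2
  ec <- expected_counts(d)
  a2 <- ec[ec$aggregation_id == "a2", ]
  expect_equal(sort(a2$expected), sort(c(0.55, 0.25, 0.2) * 1))
  # zero-filled observed for species absent from the aggregation
  expect_equal(a2$observed[a2$species == "sp2"], 0L)
  # expected counts sum to size_n per aggregation
  sums <- ec |>
    dplyr::group_by(aggregation_id) |>
    dplyr::summarise(e = sum(expected), o = sum(observed))
  expect_equal(sums$e, sums$o, tolerance = 1e-9)

  p20 <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(unname(p20 * 20), c(10, 6, 4))
})

test_that("exact pattern probability matches brute-force enumeration", {
  expect_equal(pattern_probability_exact("a", c(a = 0.5, b = 0.5), 2), 0.25)
  expect_equal(pattern_probability_exact(c("a", "b"), c(a = 0.5, b = 0.5), 2),
               0.5)
  # frozen from the enumeration oracle: 0.9^3 - 0.6^3 - 0.3^3
  p <- c(sp1 = 0.6, sp2 = 0.3, sp3 = 0.1)
  expect_equal(pattern_probability_exact(c("sp1", "sp2"), p, 3), 0.486)
  expect_equal(pattern_probability_exact(c("sp1", "sp2"), p, 3),
               enum_pattern_prob(c(1, 2), p, 3), tolerance = 1e-12)
  # single-species site: the only pattern has probability 1 for any n
  expect_equal(pattern_probability_exact("a", c(a = 1), 17), 1)
  # species with zero proportion cannot appear
  expect_equal(pattern_probability_exact(c("a", "z"),
                                         c(a = 1, z = 0), 4), 0)
  expect_error(pattern_probability_exact(character(0), c(a = 1), 2),
               "non-empty")
  expect_error(pattern_probability_exact(sprintf("s%d", 1:30),
                                         setNames(rep(1 / 30, 30),
                                                  sprintf("s%d", 1:30)), 2),
               "too large")
})

test_that("pattern probabilities over all patterns sum to one", {
  profiles <- list(c(a = 0.6, b = 0.4),
                   c(a = 0.6, b = 0.3, c = 0.1),
                   c(a = 0.4, b = 0.3, c = 0.2, d = 0.1))
  for (p in profiles) {
    for (n in c(2, 3, 7)) {
      k <- length(p)
      pats <- unlist(lapply(seq_len(k), function(m)
        utils::combn(names(p), m, simplify = FALSE)), recursive = FALSE)
      tot <- sum(vapply(pats, pattern_probability_exact, numeric(1),
                        proportions = p, n = n))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("expected richness has its closed form and enumeration agrees", {
  expect_equal(expected_richness(c(0.5, 0.5), 2), 1.5)
  p <- c(0.6, 0.3, 0.1)
  expect_equal(expected_richness(p, 3), 1.864)
  expect_equal(expected_richness(p, 3), enum_expected_richness(p, 3),
               tolerance = 1e-12)
  expect_equal(expected_richness(1, 50), 1)
})

test_that("Monte-Carlo pattern probability is seeded and converges to the exact value", {
  p <- c(sp1 = 0.6, sp2 = 0.3, sp3 = 0.1)
  mc1 <- pattern_probability_mc(c("sp1", "sp2"), p, 3, n_resamples = 10000,
                                seed = 42)
  mc2 <- pattern_probability_mc(c("sp1", "sp2"), p, 3, n_resamples = 10000,
                                seed = 42)
  expect_identical(mc1$p_value, mc2$p_value)
  se <- sqrt(0.486 * 0.514 / 10000)
  expect_lt(abs(mc1$p_value - 0.486), 4 * se)
  expect_equal(mc1$p_value_add_one,
               (mc1$p_value * 10000 + 1) / 10001, tolerance = 1e-12)
  # MC richness mean tracks the closed-form expectation
  expect_lt(abs(mean(mc1$richness_draws) - expected_richness(p, 3)),
            4 * stats::sd(mc1$richness_draws) / sqrt(10000))

  single <- pattern_probability_mc("a", c(a = 1), 5, n_resamples = 200,
                                   seed = 1)
  expect_equal(single$p_value, 1)
})

test_that("classification follows the tail rules and partitions the results", {
  expect_equal(as.character(classify_aggregation(0.20, 0.5, 0.5)), "random")
  expect_equal(as.character(classify_aggregation(0.01, 0.999, 0.002)),
               "more_species")
  expect_equal(as.character(classify_aggregation(0.01, 0.002, 0.999)),
               "fewer_species")
  expect_equal(as.character(classify_aggregation(0.03, 0.4, 0.8)),
               "other_nonrandom")

  prof <- gen_site_profile(c(a = 0.5, b = 0.3, c = 0.15, d = 0.05),
                           site = "s")
  d <- gen_null_dataset(prof, n_aggregations = 25, seed = 11)
  r <- randomize_aggregations(d, n_resamples = 800, seed = 5)
  # exactly one category per aggregation, and random iff p > alpha
  expect_false(any(is.na(r$category)))
  expect_equal(r$category == "random", r$p_value > 0.05)
  s <- summarize_categories(r)
  expect_equal(s$n_nonrandom, s$n_more + s$n_fewer + s$n_other)
  expect_equal(s$n_total, nrow(r))
})

test_that("randomization runs are deterministic and order-independent", {
  prof <- gen_site_profile(c(a = 0.6, b = 0.3, c = 0.1), site = "s")
  d <- gen_null_dataset(prof, n_aggregations = 6, seed = 2)
  r1 <- randomize_aggregations(d, n_resamples = 500, seed = 9)
  r2 <- randomize_aggregations(d[sample(nrow(d)), ], n_resamples = 500,
                               seed = 9)
  r2 <- r2[match(r1$aggregation_id, r2$aggregation_id), ]
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(as.character(r1$category), as.character(r2$category))
})

test_that("richness mode scores the number of species rather than the pattern", {
  p <- c(a = 0.45, b = 0.45, c = 0.1)
  mc <- pattern_probability_mc(c("a", "b"), p, 4, n_resamples = 20000,
                               seed = 3, statistic = "richness")
  exact_rich2 <- sum(vapply(list(c("a", "b"), c("a", "c"), c("b", "c")),
                            pattern_probability_exact, numeric(1),
                            proportions = p, n = 4))
  expect_lt(abs(mc$p_value - exact_rich2),
            4 * sqrt(exact_rich2 * (1 - exact_rich2) / 20000))
})

test_that("the binomial meta-test matches direct summation and is monotone", {
  # oracle: direct pmf summation
  direct <- function(k, n, p0) sum(stats::dbinom(k:n, n, p0))
  expect_equal(nonrandom_binomial_test(2, 47, 0.05), direct(2, 47, 0.05),
               tolerance = 1e-12)
  expect_equal(nonrandom_binomial_test(2, 47, 0.05), 0.688, tolerance = 5e-4)
  expect_equal(nonrandom_binomial_test(0, 47, 0.05), 1)
  pv <- vapply(0:47, nonrandom_binomial_test, numeric(1), n_total = 47,
               p0 = 0.05)
  expect_true(all(diff(pv) <= 1e-12))
  expect_error(nonrandom_binomial_test(3, 10, 1.2), "p0")
})

test_that("the odds contrast has its hand-computed Wald value and symmetry", {
  w <- category_odds_contrast(8, 5, 3, 47, form = "wald")
  hand <- (log(8 / 39) - log(5 / 42))^2 / (1 / 8 + 1 / 39 + 1 / 5 + 1 / 42)
  expect_equal(w$statistic, hand, tolerance = 1e-12)
  expect_equal(w$statistic, 0.79, tolerance = 5e-3)
  expect_false(w$continuity_applied)

  for (form in c("wald", "lrt")) {
    eq <- category_odds_contrast(6, 6, 3, 47, form = form)
    expect_equal(eq$statistic, 0, tolerance = 1e-12)
    expect_equal(eq$p_value, 1)
  }
  z <- category_odds_contrast(0, 5, 0, 47, form = "wald")
  expect_true(z$continuity_applied)
  expect_true(is.finite(z$statistic))
  # LRT and Wald agree to first order on balanced-ish counts
  l <- category_odds_contrast(8, 5, 3, 47, form = "lrt")
  expect_equal(l$statistic, w$statistic, tolerance = 0.05)
})
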