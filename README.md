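# aggmix

Composition null models and choice-assay analysis for multispecies animal
aggregations.

Several *Brachinus* bombardier-beetle species in riparian Arizona shelter
together by day in mixed-species groups. Given whole aggregations collected
in the field (per-species counts per aggregation per site), the central
question is whether individuals settle at random with respect to species
identity and local relative abundance. `aggmix` provides the statistical
toolkit for ecologists working with this kind of data:

* **Randomization null for composition.** For an aggregation of size *n*
  with presence/absence pattern *S* at a site with species proportions
  *p₁…p_k*, the test statistic is the pattern probability under multinomial
  sampling,

  *P(S) = Σ_{T⊆S} (−1)^{|S|−|T|} (Σ_{s∈T} p_s)^n*,

  estimated by resampling *n* individuals with replacement 10,000 times
  (`randomize_aggregations()`) and available in closed form
  (`pattern_probability_exact()`). Aggregations with *P ≤ α* are nonrandom
  and are classified as holding more species than expected, fewer, or a
  deviant species identity, via the tails of the null richness
  distribution (expected richness: *E[S] = Σᵢ (1 − (1 − pᵢ)^n)*).
* **Meta-tests.** An exact one-sided binomial test of the nonrandom
  fraction against the type-1 baseline, and a 1-df odds contrast
  (likelihood-ratio or Wald) between the more- and fewer-species
  categories.
* **Co-occurrence screens.** Pearson correlations with Fisher-z 95%
  intervals for abundant species pairs, Spearman midrank correlations for
  rare pairs (`pairwise_screen()`, `correlation_ci()`).
* **Choice assays.** Percentile-bootstrap CI (trials resampled, 10,000
  reps) for the mean proportion settling in a focal shelter, and the
  preference rule *mean > 0.5 and CI above 0.5*
  (`analyze_choice_experiments()`, `preference_decision()`).
* **Settlement dynamics.** Occupancy step-curves and completion times from
  shelter entry/exit logs (`build_occupancy_curves()`).
* **Synthetic data.** Seeded generators for site profiles, null
  (multinomial) and reinforcement-biased aggregations, binomial choice
  trials and event logs, plus `synthetic_field_survey()`, a synthetic
  stand-in matching the published marginals of the four-site field survey.

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()`,
`glance()` and `autoplot()` methods for the result objects.

## Worked example

```r
library(aggmix)

survey <- synthetic_field_survey(seed = 1)   # 47 aggregations, 4 sites
rand   <- randomize_aggregations(survey, n_resamples = 10000, seed = 1)
glance(rand)
#> # A tibble: 1 × 12
#>   n_total n_nonrandom n_more n_fewer n_other frac_nonrandom frac_more frac_fewer
#>     <int>       <int>  <int>   <int>   <int>          <dbl>     <dbl>      <dbl>
#> 1      47           4      0       1       3         0.0851         0     0.0213
```

Four of 47 null-generated aggregations are flagged at α = 0.05 — the
pipeline's empirical false-positive baseline on data where settlement
really is random (the pattern statistic is discrete, so the baseline need
not be exactly 5%). On the original field data the same pipeline flagged a
third of all aggregations.

Reconstructing a published Fisher-z interval from its coefficient and the
number of aggregation units:

```r
correlation_ci(-0.097, n_units = 59)
#> # A tibble: 1 × 4
#>        r n_units ci_lower ci_upper
#>    <dbl>   <int>    <dbl>    <dbl>
#> 1 -0.097      59   -0.345    0.163
```

A synthetic choice experiment with a true settling preference of 0.65:

```r
trials <- gen_choice_trials(0.65, n_trials = 20, seed = 2,
                            experiment_id = "demo")
analyze_choice_experiments(trials, n_boot = 10000, seed = 2) |> tidy()
#> # A tibble: 1 × 9
#>   experiment_id mean_proportion ci_lower ci_upper n_trials n_boot seed_used
#>   <chr>                   <dbl>    <dbl>    <dbl>    <int>  <int>     <int>
#> 1 demo                    0.642    0.600    0.682       20  10000 461081921
```

The mean proportion 0.642 with CI (0.600, 0.682) excludes 0.5, so the
preference rule returns `TRUE`: beetles prefer the focal shelter.

See `vignettes/aggregation-null-models.Rmd` for the full account of the
model, its assumptions and the design decisions.

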