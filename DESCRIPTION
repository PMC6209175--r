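Package: aggmix
Title: Composition Null Models and Choice Assays for Multispecies Animal Aggregations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the species composition of multispecies animal
    aggregations, built around field surveys of bombardier beetles (Brachinus)
    that shelter together in mixed-species groups. Implements a multinomial
    randomization null for aggregation composition with an exact
    inclusion-exclusion pattern-probability oracle, classification of
    aggregations as holding more or fewer species than expected, binomial and
    odds-contrast meta-tests over the classification, pairwise species
    co-occurrence screens (Pearson with Fisher-z intervals, Spearman with
    midranks), percentile-bootstrap analysis of two-shelter choice experiments,
    occupancy curves from shelter entry/exit logs, and a seeded synthetic-data
    generator (multinomial null and an occupancy-reinforced settlement
    alternative) so every stage of the pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
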