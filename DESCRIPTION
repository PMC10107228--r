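Package: scansync
Title: Behavioural Synchrony Analysis for Scan-Sampled Animal Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level behavioural synchrony analysis for single- and
    mixed-species animal groups observed by instantaneous scan sampling.
    Computes a per-scan synchrony index based on Simpson's diversity over
    behaviour counts, tests within-species synchrony against a
    weighted-resampling randomization null built from species activity
    budgets, and tests between-species synchrony with Pearson
    cross-correlations of behaviour frequencies against a pooled
    shuffle-split randomization null that treats the mixed-species group as
    one group. Includes a latent-state synthetic scan generator with
    tunable within- and between-species behavioural coupling, a full
    analysis pipeline with reproducible seeding and structured reports,
    tidy() and glance() methods for all result objects, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
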