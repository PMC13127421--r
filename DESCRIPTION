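Package: odcast
Title: Noise-Aware Small-Area Forecasting of Overdose Death Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quarterly small-area forecasting of opioid overdose
    death counts when populations are small and counts are rare. Provides a
    closed-form signal-to-noise and expected-SMAPE theory for count data
    under Normal and Bernoulli regimes with a minimal-population threshold
    solver; a synthetic area-panel generator with heavy-tailed populations
    and spatially and temporally correlated latent risk; a threshold-driven
    augmentation that grows connected synthetic regions above a population
    threshold and pools their features; an area-specific autoencoder that
    learns latent area representations with a supervised loss; a
    spatiotemporal graph neural network (graph convolutions over area
    adjacency plus an LSTM over quarters) for count prediction; and
    evaluation utilities for SMAPE/MAE/RMSE, population-bin stratification,
    and three-class trend classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
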