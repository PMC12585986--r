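Package: basinjumps
Title: Discontinuous Attractor Basin Growth in Hebbian Amari-Hopfield Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for studying how the attractor
    basin of a repeatedly presented target stimulus grows in binary
    Amari-Hopfield networks trained with a batch Hebbian rule. Provides
    exhaustive basin enumeration for small networks, sampled-state basin
    measurement for large networks, extraction of discrete basin-size jumps,
    state-transition-graph branch analysis, and maximum-likelihood fitting
    and AIC-based comparison of heavy-tailed candidate distributions
    (lognormal, exponential, half-normal, discrete power law) with bootstrap
    model-preference counts. All experiments are seeded and reproducible;
    results are returned as tidy tibbles with broom-style tidy()/glance()
    methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    withr
Config/testthat/edition: 3
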