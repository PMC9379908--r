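Package: splitN
Title: Split-Fertilization Timing Optimization for Soil-Crop Nitrogen Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A mechanistic one-dimensional soil-crop nitrogen simulator driven by
    daily precipitation, coupling Richards' equation for variably saturated water
    flow to advection-dispersion-reaction transport of nitrate, ammonium and
    organic nitrogen, with logistic maize root growth and Michaelis-Menten root
    uptake. Built around it: an exhaustive split-fertilization timing optimizer
    (uptake surfaces, precipitation-optimal pairs, close-to-optimal sets and a
    neighborhood stability metric), growing-season precipitation analytics
    (mean daily rates, rolling means, heavy-rainfall events against a reference
    percentile, one-month Standardized Precipitation Index via gamma maximum
    likelihood, drought classes, decadal summaries), a stochastic Markov-gamma
    daily weather generator, and a study pipeline correlating precipitation
    metrics with maximum nitrogen uptake and optimal fertilization timings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
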