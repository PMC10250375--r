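Package: tlinked
Title: Temperature-Linked Growth-Climate Response Analysis for Boreal Tree Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs temporally flexible, physiologically anchored
    temperature series from daily station records using the temperature-linked
    (T-linked) method, in which intra-annual periods are bounded by dates
    translated from temperature values via a five-day pass rule. Provides the
    full growth-temperature response pipeline built on such series: tree-ring
    standardization (adaptive power transformation, cubic smoothing-spline
    detrending with a 50% frequency cutoff, autoregressive prewhitening,
    biweight population chronologies), tile-grid Pearson correlation analysis
    with an adjacency-based sensitivity rule, response-structure metrics, and
    a logistic climate-boundary model that classifies and projects
    negatively- versus positively-responding forest regions in
    (temperature, precipitation) climate space. Includes synthetic generators
    for daily temperatures, ring-width networks with planted temperature
    responses, and labelled climate observations, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    grDevices,
    ggplot2,
    Matrix,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
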