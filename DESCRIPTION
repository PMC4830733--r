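Package: degopt
Title: Factorial Design Optimization of Forced-Degradation Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for planning and analysing two-level full factorial
    forced-degradation experiments in stability-indicating method development.
    Builds 2^k coded designs in standard (Yates) order, computes percent
    degradation from stressed and unstressed peak areas, screens factor
    effects with the Yates algorithm and pooled-error F tests, ranks effects
    on a Pareto chart of normalized squares, fits the coded-unit factorial
    polynomial, inverts the fitted response surface to hit a target percent
    degradation and decodes the optimum back to actual units, and provides
    ICH Q2 validation statistics (calibration regression with linearity
    ANOVA and coefficient t-tests, detection and quantitation limits,
    recovery regression, and day-grouped one-way ANOVA for intermediate
    precision).  Includes synthetic-data generators with known ground truth
    for end-to-end testing and power studies.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
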