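Package: fcaequity
Title: Floating Catchment Area Accessibility Scores and Equity Assessment
    for Health Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes geographic accessibility scores for health-service
    resources with five methods: the regional average method, the two-step
    floating catchment area (2SFCA) method, and three three-step (3SFCA)
    variants whose facility-choice probabilities weight a piecewise
    distance-decay kernel by facility capacity, by consumer ratings on a
    1-5 scale, or by both. Scores feed a distributional-fairness toolkit:
    per-group summary statistics, population-weighted Lorenz curves and
    Gini coefficients with a five-level equity scale, quintile map classes,
    and a three-stage policy prioritization of administrative regions.
    Includes a seeded synthetic-landscape generator emulating clustered
    urban supply and log-normal town populations, CSV/GeoJSON input and
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
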