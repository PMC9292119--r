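Package: gmarginal
Title: Marginal Effect Estimates via Parametric G-Computation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates marginal (population-standardized) effect measures
    for time-fixed exposure-outcome data using parametric g-computation
    with generalized linear models and percentile-bootstrap confidence
    intervals. For binary outcomes it reports the risk difference, risk
    ratio, odds ratio and number needed to treat; for count and rate
    outcomes (Poisson or negative binomial, with person-time offsets) the
    incidence rate difference and ratio; for continuous outcomes the mean
    difference. Supports categorical and continuous exposures, subgroup
    (effect measure modification) analysis, cluster-level bootstrap
    resampling, a synthetic cohort generator with known true marginal
    effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    parallel,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
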