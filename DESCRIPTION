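Package: weathercrime
Title: Causal Analysis of Weather Effects on Daily Crime Counts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs hypothetical randomized experiments from daily
    weather and crime-incident tables to estimate finite-population average
    exposure effects of heat index and rainfall on daily crime counts.
    Days are segmented into heat-index classes, assigned binary exposure
    arms by a threshold rule, matched one-to-one on a caliper around the
    estimated propensity score without ever reading the outcome, and the
    missing potential outcomes are then multiply imputed from per-arm
    Bayesian negative-binomial regressions with weakly informative priors,
    yielding a posterior for the average exposure effect over the matched
    days.  Includes a synthetic-data generator that stores both potential
    outcomes per day, so the pipeline can be validated against exact
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
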