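Package: dawols
Title: Days Alive Without Life Support and Similar Inflated Count Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for defining and analysing days alive without life
    support (DAWOLS), days alive and out of hospital, and similar zero- and
    maximum-inflated count outcomes from randomised clinical trials.
    Constructs outcomes from daily patient-state records under explicit
    death-handling and follow-up rules, fits four regression families from
    their likelihoods (linear, hurdle negative binomial, zero-one-inflated
    beta, cumulative logistic with a death category), derives common
    estimands (group mean outcomes, mean differences, ratios of means,
    cumulative odds ratios) with 95% percentile intervals over
    parametric-bootstrap draws, provides model-fitness diagnostics (RMSE,
    MAE, predicted-versus-observed mean gaps, predictive checks, a
    proportional-odds diagnostic), visualises outcome distributions and
    daily state occupancy, and ships a seeded synthetic-trial generator
    emulating the characteristic inflation at the minimum (deaths) and
    maximum (follow-up truncation) values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
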