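Package: migrainecea
Title: Cost-Effectiveness Modelling of Preventive Migraine Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic modelling of preventive migraine treatment:
    a 12-week decision tree feeding a two-state Markov cohort model
    (on-treatment responders versus discontinuation, with background
    mortality) over a 10-year horizon.  Utilities and costs are driven by
    monthly migraine days (MMD) through a linear utility model and
    band-structured resource use; outcomes are discounted costs,
    quality-adjusted life years and migraine days, summarised as
    incremental cost-effectiveness ratios.  Includes deterministic
    (tornado, scenario) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic patient-level
    data generator so regression fitting and model validation run without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    MASS,
    sandwich,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
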