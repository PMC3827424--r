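Package: obesitysim
Title: Two-Stage Obesity Projection and Chronic-Disease Microsimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects population body-mass-index (BMI) category trends with a
    constrained multinomial regression and feeds the projections into an
    individual-level Monte Carlo microsimulation of six obesity-related
    chronic diseases (coronary heart disease & stroke, obesity-related
    cancers, hypertension, type 2 diabetes, knee osteoarthritis). Includes
    illness-death (DisMod-style) prevalence-to-incidence conversion,
    relative-risk calibration of BMI-category-specific incidence, population
    attributable fraction accounting, intervention scenarios that reduce
    population BMI by a fixed percentage, direct healthcare-cost tallies and
    ratio-based indirect cost extrapolation, plus a synthetic-data generator
    emulating sparse national BMI survey series so the whole pipeline is
    testable without access to the original national datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ggplot2,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
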