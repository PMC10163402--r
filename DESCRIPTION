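Package: stepdyn
Title: Person-Specific Dynamical Modeling of Step-Count Responses to
    Motivational Messages
Version: 0.1.0
Authors@R:
    person("stepdyn", "maintainers", email = "stepdyn@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing minute-level wearable step-count data from
    digital messaging interventions with autoregressive-with-exogenous-input
    (ARX) system identification. Provides a synthetic cohort generator that
    emulates a six-month just-in-time messaging protocol (0-6 messages per
    day from three content libraries, availability windows of at least ten
    hours, realistic wear-time missingness), preprocessing of minute-level
    step and heart-rate streams into 15-minute epoch series, per-participant
    switched weekday/weekend ARX model fitting by least squares, simulation
    of impulse and cumulative step responses with bootstrap error bounds,
    extraction of seven control-systems response features, and group-level
    feature statistics (two-way repeated-measures ANOVA with
    Greenhouse-Geisser correction and generalized eta squared, Friedman
    tests with Kendall W, Bonferroni-corrected pairwise post hocs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
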