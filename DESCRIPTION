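Package: laterace
Title: LATER Race-Model Analysis of Self-Paced Inter-Movement Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling self-paced inter-movement intervals with the
    LATER (linear approach to threshold with ergodic rate) family of race
    models. Provides the recinormal (reciprocal-normal) distribution with
    closed-form maximum-likelihood fitting, reciprobit transformation and
    plotting, a minor-early-component Gaussian mixture on the promptness
    scale, constrained two-condition joint fits (null, shift, swivel,
    unconstrained) compared by the Bayesian information criterion with
    Kass-Raftery evidence labels, a bootstrap estimator of the decision
    threshold ratio, a race-trial and stimulation-experiment simulator, and a
    pipeline converting timestamped event streams to labelled intervals with
    frequency statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
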