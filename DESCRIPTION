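Package: riskaim
Title: Risk-Sensitive Aim-Point Optimality in Duration and Distance Reproduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-theoretic analysis of risky magnitude reproduction.
    Models a responder as a Gaussian aim point with endogenous noise, computes
    expected gain under block-wise asymmetric payoff schemes (reward for
    landing in a symmetric window around a target duration or distance,
    penalties for responding too early or too close), derives optimal aim
    points and expected-reward surfaces, filters trial-level data with a
    median-absolute-deviation rule, and scores each participant's adjustment
    against the optimum as optimality and efficiency statistics. A cross-modal
    regression with participant-clustered bootstrap confidence intervals tests
    whether under- or over-adjustment is shared between timing and distance
    estimation. A synthetic-cohort generator with controllable ground truth
    (noise, bias, adjustment propensity, contaminant rate) makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
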