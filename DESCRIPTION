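Package: patsteps
Title: Reproducibility Analysis for Activity-Tracker Step Counts Under a
    Low-Impact Gait Protocol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating how reliably physical activity trackers
    count low-impact steps under a structured 14-condition walking protocol
    (varying step size, direction, walking aids and footwear). Implements
    step-count ratios with the study's exclusion rules, banded weighted
    agreement rates and Cohen-style kappa for intra- and inter-rater
    reproducibility, intraclass correlation from condition-random-effect
    REML models with suppression rules, zero-inflated negative binomial
    condition-effect models with cluster-robust (Huber-White) inference and
    marginal-mean contrasts, and a seeded synthetic-data generator that
    reproduces the statistical structure of such experiments so the whole
    pipeline is testable without the original trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    ggplot2,
    stats,
    utils
Suggests:
    glmmTMB,
    MASS,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
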