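Package: amcgc
Title: Adaptive Mixture Categorization and G-Computation for Exposure Mixtures
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Estimates joint effects of exposure mixtures on health outcomes
    by first categorizing each continuous exposure with an adaptive search
    that minimizes the reciprocal of the one-way ANOVA F statistic (growing
    the number of categories by a linear search with an F-test p-value
    stopping rule), and then applying g-computation to the categorized
    exposures to obtain a joint mixture effect and direction-normalized
    per-term weights with bootstrap confidence intervals.  Includes a
    fixed-quantile categorization baseline, a latent-state mixture-of-normals
    data simulator with bias and variable-selection (TPR/FPR) study runners,
    preprocessing utilities for trace-element concentration tables
    (limit-of-detection imputation, log transformation), a synthetic
    case-control application fixture, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
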