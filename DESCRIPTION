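Package: famrisk
Title: Familial Lung-Cancer Risk Models from Matched Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for familial-aggregation case-control analyses of lung
    cancer risk: crude odds ratios with Woolf confidence intervals and the
    usual contingency-table tests, conditional logistic regression for
    spouse-matched pairs, forward stepwise unconditional logistic regression
    (score-test entry, likelihood-ratio removal), recalibration of the
    case-control intercept to a population incidence prior, enumeration of
    covariate strata into absolute-risk and relative-risk tables with
    epidemiological risk bands, and cutoff-based classification validation.
    Includes a seeded generator of synthetic spouse-matched cohorts so every
    stage of the pipeline is testable without access to raw family data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
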