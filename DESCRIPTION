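Package: lcatrends
Title: Multi-Group Latent Class Analysis of Categorical Survey Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multi-group latent class models to repeated cross-sectional
    categorical survey data, with survey weights, school-level clustering and
    covariate-predicted class membership. Supports measurement-invariance
    regimes (fully unconstrained, semi-constrained, fully constrained) across
    survey waves, sample-size-adjusted BIC model selection over class counts,
    multiple imputation of missing covariates with Rubin's rules pooling,
    label-switching repair, cluster-robust sandwich inference for covariate
    odds ratios, and a calibrated synthetic cohort generator for end-to-end
    testing of the full four-stage workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    nnet,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
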