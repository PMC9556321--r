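Package: bopmeta
Title: Burden-of-Proof Dose-Response Meta-Regression and Evidence Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits non-linear exposure-response relative-risk curves from
    study-level dose-response tables using shape-constrained quadratic splines
    with trimmed weighted least squares, scales them through a linear
    mixed-effects meta-regression with study-design bias covariates and a
    Fisher-information correction for between-study heterogeneity, screens for
    small-study effects with a modified Egger's regression, and summarises the
    strength of evidence through the burden-of-proof risk function (BPRF),
    risk-outcome score (ROS), star rating, and theoretical minimum risk
    exposure level (TMREL). Includes a synthetic cohort generator emulating
    the category-comparison structure of extracted dose-response literature
    for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
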