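Package: netcea
Title: Trial-Based Cost-Effectiveness Analysis with Bootstrapped ICERs and Acceptability Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for economic evaluation alongside
    two-arm randomized trials, built around the comparison of guided
    Internet-based therapy with unguided Internet-based self-help for harmful
    alcohol use. Provides societal and health-care-provider costing (therapist
    time, software, participant leisure time, SF-HLQ absenteeism and
    presenteeism under the human-capital approach, and macro-level additional
    societal costs), a composite treatment-response outcome and EQ-5D QALYs
    under the Dolan MVH-A1 UK tariff, multiple imputation of missing follow-up
    data by a bootstrap-EM multivariate-normal model with Rubin's rules
    pooling, stratified nonparametric bootstrapping of incremental costs,
    effects and cost-effectiveness ratios, cost-effectiveness planes and
    acceptability curves, deterministic scenario sensitivity analysis, and a
    seeded synthetic trial generator for fully reproducible end-to-end runs.
License: MIT
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
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
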