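Package: gsbinom
Title: Group-Sequential Designs for Two-Arm Binomial Trials with
    Stratified Randomization and Toxicity Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design calculators and a patient-level simulator for one-sided
    group-sequential two-arm trials with binary endpoints, as used in
    Phase II/III studies of therapeutic interventions in hospitalized
    COVID-19 patients. Implements power-family (Kim-DeMets) error-spending
    functions for efficacy and futility, stopping boundaries computed by
    first-passage recursion of the canonical sequential normal statistic,
    maximum-information sample sizes for unequal allocation with unpooled
    variances, sequential binomial toxicity stopping boundaries with an
    exact path-recursion calibrator, WHO-ordinal-scale risk grouping with
    Zelen stratified permuted-block randomization, stratified one-sided
    z-tests for interim decisions, and Monte-Carlo estimation of operating
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
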