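Package: netbenefit
Title: Net Benefit Regression for Trial-Based Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing person-level cost-effectiveness data from
    randomised trials with the net benefit regression framework. Estimates
    incremental cost, incremental effect and the incremental cost-effectiveness
    ratio (ICER) by ordinary least squares on a treatment indicator, sweeps the
    incremental net benefit (INB) across a willingness-to-pay grid, extracts
    Fieller-style confidence limits for the ICER from the INB confidence
    bounds, builds parametric and bootstrap cost-effectiveness acceptability
    curves (CEACs), and fits treatment-by-subgroup interaction and stratified
    models. Includes a seeded synthetic-trial generator with known incremental
    truths for validation, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    tibble,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
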