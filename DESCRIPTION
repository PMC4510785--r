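Package: diabcea
Title: Cost-Utility Analysis of Intensive Multifactorial Treatment in
    Screen-Detected Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based and model-based cost-utility analysis of
    early intensive multifactorial treatment versus routine care in
    screen-detected type 2 diabetes. Provides a synthetic two-arm cohort
    generator with exponential first-cardiovascular-event times, an
    intervention micro-costing ledger with 3.5 percent discounting, an
    additive cost and utility-decrement valuation engine, covariate-adjusted
    incremental cost-effectiveness estimation, multivariate-normal multiple
    imputation with Rubin's rules, a configurable UKPDS-style patient-level
    outcomes microsimulation for 10-30 year extrapolation, and decision
    uncertainty analysis (cost-effectiveness plane, acceptability curves,
    tornado diagrams, threshold and scenario analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
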