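Package: strataMR
Title: Non-Linear Mendelian Randomisation from Stratified Summarised Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage non-linear Mendelian randomisation. Stage one
    converts individual-level data (genetic instrument, exposure, outcome)
    into stratified summarised data by stratifying on the residual
    exposure and computing per-stratum instrument-exposure and
    instrument-outcome associations. Stage two estimates the
    exposure-outcome causal curve from those summaries alone, via
    fractional-polynomial meta-regression of localised average causal
    effect (LACE) estimates or a continuous piecewise-linear construction,
    with parametric-bootstrap confidence intervals, non-linearity tests,
    and instrument-homogeneity diagnostics. Includes a synthetic data
    generator with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
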