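Package: cvdrecal
Title: Recalibration and Validation of 10-Year Cardiovascular Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coefficient-driven 10-year cardiovascular risk engines
    (Framingham ATP-III with local baseline-survival substitution, the
    Pooled Cohort Equations, and SCORE2 with regional rescaling),
    cloglog-scale recalibration through sex- and ethnicity-specific
    rescaling factors, and an evaluation suite for censored survival
    outcomes: Harrell's concordance index, calibration-in-the-large and
    calibration slope in a Poisson framework, analysis-of-deviance
    goodness-of-fit, observed-versus-predicted quintile tables, and
    decision-curve net benefit.  A synthetic multi-ethnic cohort
    generator allows every stage to be exercised end-to-end without
    access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
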