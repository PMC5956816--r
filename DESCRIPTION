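Package: mriv
Title: Two-Sample Mendelian Randomisation with Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation from GWAS summary
    statistics: harmonisation of exposure and outcome associations (including
    proxy-variant substitution), instrument-strength diagnostics (F-statistics,
    variance explained, the I2GX no-measurement-error statistic),
    inverse-variance weighted estimation with fixed and multiplicative
    random-effects standard errors, Cochran's Q heterogeneity testing, the
    weighted median estimator with parametric-bootstrap standard errors,
    MR-Egger regression with SIMEX dilution correction,
    heterogeneity-penalised model averaging over instrument subsets,
    leave-one-out sensitivity analysis, multi-outcome screening, and a
    synthetic-data generator with known causal truth for estimator validation.
    Ships the six-variant serum-magnesium / coronary-artery-disease instrument
    set as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
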