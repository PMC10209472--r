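Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomisation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomisation (MR)
    with GWAS summary statistics. Reads and harmonises per-variant effect
    estimates across exposure and outcome studies (allele alignment,
    palindromic-variant resolution, LD-proxy substitution, instrument-strength
    screening), estimates causal effects via Wald ratios pooled by fixed- and
    random-effects inverse-variance weighting, weighted median, weighted
    mode-based and MR-Egger regression with SIMEX correction for regression
    dilution, and diagnoses pleiotropy through Cochran's Q, the I-squared
    index with test-based confidence intervals, per-variant Q contributions
    with outlier removal, and leave-one-out sensitivity analysis. A seeded
    synthetic summary-statistics generator with configurable pleiotropy
    supports parameter-recovery experiments and calibration checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
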