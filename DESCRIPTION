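Package: trialmr
Title: Factorial-Trial Metabolome Screening and Two-Sample Mendelian
    Randomisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intention-to-treat screening of NMR metabolomics panels across
    factorial randomised-trial arms with heteroskedasticity-consistent
    inference and a principal-component-based multiplicity threshold;
    two-stage least squares estimation of biomarker dose effects using
    randomisation arms as instruments; and a two-sample Mendelian
    randomisation engine operating on GWAS summary statistics, with allele
    harmonisation, inverse-variance-weighted, MR-Egger and weighted-median
    estimators, and per-variant instrument-strength diagnostics. A
    synthetic-data generator emulates a 3x3 factorial dietary trial over
    correlated metabolic traits and paired exposure/outcome summary
    statistics with known causal effects, so every stage has a
    ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
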