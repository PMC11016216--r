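Package: protMR
Title: Proteome-Wide Mendelian Randomization Screening with Colocalization
    and Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for proteome-wide causal screening from GWAS
    summary statistics: selection of cis/trans pQTL instruments (genome-wide
    significance, MHC exclusion, greedy LD clumping, cross-protein pleiotropy
    and weak-instrument filters, LD proxy lookup), exposure-outcome allele
    harmonization, two-sample Mendelian randomization estimators (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median, weighted mode) with
    Cochran's Q heterogeneity and Egger-intercept pleiotropy tests, Bayesian
    colocalization via Wakefield approximate Bayes factors (PPH0-PPH4), and
    two-step mediation analysis (product of coefficients with delta-method
    uncertainty and a reverse-MR validity check). Ships a synthetic GWAS
    summary-statistics generator with known causal structure so that every
    stage of the screen can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coloc.R'
    'instrument-selection.R'
    'io.R'
    'mediation.R'
    'mr-estimators.R'
    'scenarios.R'
    'screen.R'
    'synthetic-gwas.R'
    'utils.R'
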