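Package: pvmr
Title: Pharmacovigilance Signal Detection and Two-Sample Mendelian
    Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines spontaneous adverse-event reporting system extracts
    (FAERS/JADER/CVARD-like tables) for drug-event disproportionality
    signals using the reporting odds ratio, proportional reporting ratio
    and Bayesian information component, triages detected signals with a
    semiquantitative clinical-priority score, and models report-level
    risk factors by logistic regression.  A companion two-sample
    Mendelian randomization suite estimates causal effects from GWAS
    summary statistics (inverse-variance weighted, MR-Egger, weighted
    median, mode-based estimators) with instrument selection by LD
    clumping and F-statistics, heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO) and leave-one-out
    sensitivity analysis.  Seeded generators for both spontaneous-report
    and GWAS summary data support calibration and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
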