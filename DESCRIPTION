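Package: seroscreen
Title: Two-Phase Autoantibody Array Screening and Diagnostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for proteome-array autoantibody studies in rheumatoid
    arthritis and related autoimmune cohorts. Reads and writes GenePix-style
    array layouts (GAL dialect), per-sample scan results (GPR dialect) and
    cohort manifests; aggregates duplicate spots into a samples-by-probes
    intensity matrix with reproducibility (RPD) and signal-to-noise (SNR)
    annotations; performs Phase-I array quality control, hit calling against
    blank and secondary-antibody-only controls, and candidate-antigen
    selection; Phase-II diagnostic evaluation with mean-plus-2SD
    seropositivity cutoffs, nonparametric ROC/AUC with DeLong confidence
    intervals, subgroup prevalence tests and clinical correlation with
    Bonferroni correction; and an RBF-kernel SVM classifier with recursive
    feature elimination and a decision threshold calibrated at fixed
    training specificity. A synthetic-cohort generator with known ground
    truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    Rtsne,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
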