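Package: lupusnr
Title: Molecular and Cellular Analysis of Non-Response to Lupus Nephritis Therapies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dissecting drug non-response in longitudinal
    lupus nephritis cohorts: sustained-response labelling from SLEDAI/PGA (SRI-4)
    and urine protein-creatinine trajectories, covariate-adjusted moderated
    differential expression with empirical-Bayes variance shrinkage and a
    consensus intra-patient correlation, GSEA-based signature comparison and
    up/down expression-ratio scoring, reference-based cell-type deconvolution
    with rich/poor stratification, single-cell QC and control-binned module
    scoring, mechanistic signalling-circuit propagation with in-silico target
    inhibition, and patient-grouped stratified nested cross-validation scored
    by the Matthews correlation coefficient. A synthetic-data generator with
    known ground truth makes every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite,
    tools,
    generics,
    MASS,
    class,
    e1071,
    nnet,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
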