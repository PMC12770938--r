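Package: mdmscreen
Title: Methylated DNA Marker Panels and Arm-Level Aneuploidy Scoring for
    Esophageal Neoplasia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and filtering methylated DNA markers
    (MDMs) that discriminate high-grade dysplasia and esophageal
    adenocarcinoma from nondysplastic Barrett's esophagus, and for scoring
    chromosome-arm aneuploidy from shallow whole-genome 1-Mb bin counts.
    Includes overdispersed logistic differential-methylation statistics
    with an AUC/fold-change/background-noise filter cascade, read-level
    epiallele concordance filtering, control-variability coefficient-of-
    determination marker reduction, pooled-reference log2-ratio copy-number
    segmentation by a three-state hidden Markov model with segment-size
    weighted-median arm calls, cross-validated random-forest and exhaustive
    4-marker logistic evaluation with bootstrap optimism correction, DeLong
    AUC comparisons, rule-out threshold analysis and screening
    NPV/PPV projection. A synthetic cohort generator with planted marker
    and arm-event truth supports end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    mgcv,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
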