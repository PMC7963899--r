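Package: adabscreen
Title: Autoantibody Biomarker Discovery for Anti-Drug-Antibody Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for autoantibody protein-microarray
    profiling aimed at predicting anti-drug-antibody (ADAb) development under
    adalimumab therapy in rheumatoid arthritis. Processes spot-level array
    intensities (quadruplicate protein spots, Cy3-BSA and IgG-dilution
    controls) into per-sample expression matrices, applies composite
    quantile/control-anchored normalization and fold-change computation,
    screens biomarkers by penetrance fold change and penetrance frequency,
    filters candidates by per-antigen ROC AUC at two timepoints, merges
    cohorts with parametric empirical-Bayes batch adjustment, and selects
    biomarker panels by recursive feature elimination over random-forest
    Gini importance with iterated random-forest stability assessment.
    Includes clinical utilities (ADAb positivity rule, EULAR response
    classification, grouped clinical summaries) and a seeded
    synthetic-cohort generator that emulates the study design for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    limma,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
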