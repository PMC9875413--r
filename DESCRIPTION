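Package: exhaustscope
Title: PET Radiomics Modelling of Tumor-Infiltrating CD8+ T Cell Exhaustion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether the spatial heterogeneity of FDG uptake on
    PET images carries information about the exhaustion state of
    tumor-infiltrating CD8+ T cells. The package simulates tumor-bearing 3D
    PET/CT phantoms whose local uptake heterogeneity is coupled to a latent
    terminally-exhausted T cell fraction, converts activity images to
    standardized uptake values, extracts first-order, shape, gray-level
    co-occurrence and run-length radiomic features, filters them by
    test-retest concordance (Lin's CCC), selects exhaustion-correlated
    features by LASSO, and fits a three-feature binary logistic T-exhaustion
    score evaluated by concordance index, Brier score and calibration curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
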