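Package: cravingsig
Title: Craving Prediction and Voxel Signatures from fMRI Drug Cue Reactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested analysis pipeline for predicting block-level drug
    craving ratings from voxelwise beta-coefficient maps acquired during
    fMRI drug cue reactivity tasks. Implements variance filtering,
    standardization and PCA or ANOVA feature reduction fit on training
    data only; a menu of regression estimators with subject-level
    cross-validated grid search; permutation-null significance testing
    with bootstrap confidence intervals and normality-gated effect sizes;
    back-projection of the fitted reduced-space model into voxel space
    (the VB signature) with atlas-based regional summarization; and
    derived high/low-craving and cue-type classifiers. Ships a synthetic
    cohort generator that emulates the block design, sparse
    high-dimensional beta maps and rating structure of cue-reactivity
    studies, so the entire pipeline is testable without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    glmnet,
    randomForest,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
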