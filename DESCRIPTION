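Package: rccradiomics
Title: Multiphase CT Radiomics Pipeline for Renal Cell Carcinoma Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for predicting renal cell carcinoma (RCC)
    histological subtype (clear cell, papillary, chromophobe) from 3D
    multiphase contrast-enhanced CT radiomic features. Provides a seeded
    synthetic multiphase-CT cohort generator, extraction of 105 radiomic
    features per phase (first-order, 3D shape, GLCM, GLRLM, GLSZM, GLDM,
    NGTDM), inter-rater ICC reproducibility filtering, ensemble bagged-LASSO
    stability selection, one-vs-rest logistic subtype models with repeated
    stratified cross-validation, a clinical-variable control model, and
    confusion-matrix/ROC/DeLong evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
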