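Package: radiomaps
Title: Parametric Radiomics Feature Maps for Prostate MRI with a Full
    Statistical Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes grid-wise parametric radiomics feature maps from 3D
    T2-weighted prostate MRI volumes: the image is tiled into small cells
    (default 2 x 2 x 3 mm), 93 first-order and texture features (GLCM, GLDM,
    GLRLM, GLSZM, NGTDM) are computed per cell into spatially registered
    maps, and lesion volumes of interest are transferred into map space to
    extract per-feature map means. Includes a synthetic prostate-phantom
    cohort generator with dual-rater masks and clinical covariates, and the
    downstream statistical analysis: Mann-Whitney U screening, univariate
    logistic models with ROC analysis, bivariate ridge models combining map
    features with PSA density (continuous and 0.15/0.20 cutoffs) under class
    upsampling and bootstrap, DeLong AUC comparison, and ICC(3,1) interrater
    reliability, stratified by prostate zone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    pROC,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
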