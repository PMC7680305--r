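Package: lnrad
Title: CT Radiomics Pipeline for Lymph Node Metastasis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable CT-radiomics pipeline for predicting
    histologically confirmed lymph node metastasis from segmented
    contrast-enhanced CT lymph nodes. Provides a synthetic CT phantom
    cohort generator, isotropic B-spline resampling and fixed-bin-width
    discretization, an IBSI-style 156-feature panel (first-order, 3D
    shape, five gray-level texture-matrix families) plus a 3D local
    binary pattern filter with level-1, level-2 and kurtosis maps,
    segmentation-agreement (Dice) and ICC(3,1) feature-robustness
    filtering, parametric empirical-Bayes batch harmonization across
    scanners, LASSO-penalized logistic models with cross-validated
    penalty selection and maximally selected rank-statistic cutpoints,
    and evaluation by bootstrap ROC, paired AUC comparison, calibration
    and lymph-node-level decision curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
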