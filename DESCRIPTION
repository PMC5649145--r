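Package: mcisubtype
Title: Stability Feature Selection and Ensemble Classification of MCI
    Subtypes from Morphometric MRI Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for classifying mild cognitive impairment
    (MCI) subtypes from cross-sectional and longitudinal tables of
    MRI-derived morphometric measurements (sulcal width, cortical
    thickness, regional gray-matter volume, subcortical volume, and
    white-matter-hyperintensity volume).  Implements stability feature
    selection by subsampling frequency (ANOVA-F filter plus SVM recursive
    feature elimination over repeated half-splits), hybrid class
    rebalancing (iterated k-means centroid oversampling of the minority
    class and k-medoids undersampling of the majority class), a weighted
    soft-voting ensemble of an RBF support vector machine, logistic
    regression and random forest, and Monte Carlo (stratified
    shuffle-split) cross-validated evaluation with ranked-biomarker
    frequency reporting.  A synthetic-cohort generator with planted,
    known-truth group effects supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    glmnet,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
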