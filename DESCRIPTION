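Package: nirsisc
Title: Inter-Subject Correlation Analysis for Naturalistic fNIRS Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for functional near-infrared spectroscopy
    (fNIRS) recordings acquired under naturalistic (narrative) stimulation.
    Converts raw light intensities to oxy-/deoxy-hemoglobin concentration
    changes via the modified Beer-Lambert law with age- and
    wavelength-dependent differential pathlength factors, corrects motion
    artifacts with a hybrid spline/wavelet algorithm, removes scalp
    physiology by PCA-based short-channel regression, computes leave-one-out
    inter-subject correlations (ISC), tests them against phase-scrambled
    surrogate nulls with max-statistic family-wise correction, quantifies
    single-participant reproducibility with a normalized-dot-product
    consistency statistic, decodes stimulus condition with a weighted-voting
    classifier ensemble under permutation testing, and relates hemoglobin
    dynamics to continuous suspense ratings through a nuisance-controlled
    GLM. Includes a synthetic cohort generator with ground truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    e1071,
    glmnet,
    kernlab,
    randomForest,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
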