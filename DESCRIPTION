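Package: dlmvoi
Title: Deep-Learning-Masked Auto-Fixed VOI Radiomics for Prostate MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic lesion volume-of-interest (VOI) placement and
    radiomics modelling for biparametric prostate MRI. From a single click on
    the apparent diffusion coefficient (ADC) map, the package repositions the
    seed to the lowest-ADC voxel with an outlier-robust neighbourhood search,
    rasterizes a fixed-diameter sphere in physical millimetres, intersects it
    with a whole-prostate mask (with an index-voxel quality check), extracts
    first-order and five families of forced-2D gray-level texture features,
    selects features by joint mutual information maximization, and trains a
    Bayesian-optimized gradient-boosted classifier of clinically significant
    prostate cancer under a nested cross-validation objective. A seeded
    synthetic multi-center bpMRI phantom generator makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pROC,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
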