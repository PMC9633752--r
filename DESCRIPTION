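Package: deltarad
Title: MRI Delta-Radiomics for Local Control Prediction After MR-Guided Liver SBRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end delta-radiomics analysis of longitudinal MR setup
    images acquired during MR-guided stereotactic body radiotherapy (SBRT) of
    liver lesions. Provides NIfTI volume and mask ingestion, region-of-interest
    intensity normalization (mean +/- 3 sigma clipping) and 64-level
    histogram-equalization quantization, 39 second-order three-dimensional
    texture features from gray level co-occurrence, run length, size zone and
    neighborhood gray tone difference matrices, biologically effective dose
    (BED) checkpoint alignment across heterogeneous fractionation schedules,
    delta-feature construction at BED 20 Gy and 40 Gy, random-forest Gini
    feature ranking, bootstrapped logistic-regression internal-validation AUC,
    and a seed-deterministic synthetic longitudinal cohort generator for
    testing every pipeline stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    igraph
Config/testthat/edition: 3
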