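Package: DLRadiomics
Title: Deep-Learning Radiomics for Predicting Early Tumor Regression on
    Planning CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for predicting early radiotherapy-induced gross tumor
    volume (GTV) regression from pre-treatment planning CT. Converts a CT
    volume plus GTV segmentation into a model-ready 2D tumor crop (isotropic
    nearest-neighbour resampling, maximum-area slice, center-of-gravity
    cropping, background masking, soft-tissue windowing, bilinear resize),
    extracts fixed-length deep feature vectors through a pluggable frozen
    convolutional-backbone contract (with a deterministic stub backbone) and
    a 107-feature handcrafted radiomics backend, performs two-step feature
    selection (ICC(3,1) robustness over multiple segmentations, Spearman
    collinearity pruning, and five filter rankers: chi-square, Wilcoxon,
    neighbourhood component analysis, ReliefF, infinite feature selection),
    and evaluates 5 ranker x 5 classifier model grids with the 0.632+
    bootstrap AUC, greedy forward feature selection, corrected resampled
    paired t-tests, and imbalance-aware threshold sweeps. Includes synthetic
    phantom, multi-segmentation, and feature-cohort generators so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    png,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
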