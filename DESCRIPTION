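Package: percistnet
Title: PERCIST-Guided Tissue Classification and Lesion Detection in FDG PET/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An automated workflow for tissue classification and breast-cancer
    lesion detection in [18F]FDG PET/CT. Implements PERCIST v1.0 liver-referenced
    thresholding with SUL quantification, threshold-driven candidate segmentation
    and Round-Robin constrained region growing for training-label generation,
    fixed-geometry two-channel slice preprocessing, a compact 2D U-Net pixel
    classifier with class-weighted cross-entropy trained by stochastic gradient
    descent with momentum, PERCIST follow-up-threshold post-processing, and
    voxel- and study-level evaluation (confusion matrices, Dice, Jaccard,
    percent difference in SUL-Max). A synthetic PET/CT phantom generator with
    exact ground-truth labels makes the whole pipeline testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
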