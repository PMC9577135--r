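Package: alseg
Title: Active Learning for Multi-Class Histology Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Human-in-the-loop active learning for semantic segmentation of
    H&E histology regions of interest (ROIs). Provides color-legend label-map
    encoding and decoding, patient-level cohort splitting, resolution and
    intensity preprocessing, a compact encoder-decoder (U-net style)
    convolutional segmentation network trained with masked categorical
    cross-entropy, a quality-assurance-grade-driven sample selection loop with
    a triplicate random-learning control, pooled per-class Sorensen-Dice and
    one-vs-all ROC/AUC evaluation, and a synthetic ROI cohort generator that
    emulates the class structure of annotated oral cavity carcinoma tissue so
    the full pipeline is exercisable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
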