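Package: livertex
Title: Texture Radiomics for 2-D Lesion ROIs with Reproducibility-Driven
    Feature Selection and Classifier Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A 2-D region-of-interest radiomics pipeline for grayscale
    image slices with binary lesion masks: adaptive Wiener denoising,
    fixed-bin-number gray-level discretization, 233 texture features from
    six families (intensity histogram, gray-level co-occurrence, gray-level
    gradient co-occurrence, run-length, Gabor wavelet, intensity-size-zone),
    test-retest reproducibility filtering (Lin's concordance and dynamic
    range), redundancy pruning, Kruskal-Wallis screening with ROC cut-offs,
    and four-classifier evaluation with bootstrap stability (relative
    standard deviation of AUC). Includes a synthetic lesion-phantom
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class,
    e1071,
    jsonlite,
    nnet,
    png,
    RNifti
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
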