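Package: sfcnfmri
Title: Decoding Tactile Illusion Percepts from Task fMRI with a Lightweight
    3D CNN and Grad-CAM ROI Saliency Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates block-design tactile-illusion fMRI experiments
    (randomized Aristotle / Reverse / Asynchronous stimulation trials with
    button-press percept reports), generates synthetic 4D BOLD volumes with
    class-discriminative signal confined to designated atlas regions, trains
    a simple fully convolutional network (SFCN) on perception-based and
    stimulus-based binary decoding tasks under trial-grouped cross-validation
    with majority-class undersampling, computes Grad-CAM saliency maps from
    the last convolutional layer, and localizes percept-discriminative brain
    regions with grand-mean ROI statistics (Wilcoxon signed-rank tests with
    Benjamini-Hochberg false discovery rate correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
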