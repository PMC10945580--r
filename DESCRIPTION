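Package: punctaseg
Title: Segmentation and Quantification of Synaptic Puncta in 3D Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An image-in, analysis-out pipeline for punctate fluorescent
    signals in 3D microscopy stacks, built around the reporters used to
    visualize synapses in C. elegans. Provides a 2.5D U-Net for masking
    neurites from a cytoplasmic channel, a two-layer local-feature pixel
    classifier (random forest, SVM, or MLP) with hard-negative mining for
    segmenting synaptic puncta, connected-component quantification of
    punctum number, volume and intensity, skeleton-referenced spatial
    distribution profiles, IoU benchmarking utilities, and a synthetic
    stack generator with voxel-level ground truth so the whole pipeline is
    testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    nnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
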