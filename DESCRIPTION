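Package: dognet
Title: Trainable Difference-of-Gaussians Networks for Synaptic Puncta
    Detection in Multiplexed Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of synaptic puncta in multi-channel fluorescence
    microscopy images with shallow and deep DoGNets: small convolutional
    networks whose kernels are reparameterized as Differences of Gaussians
    (isotropic, anisotropic, or 3D), trained end-to-end against point
    annotations with a soft-Dice loss.  Includes grid initialization of the
    filter bank, an element-wise product layer combining presynaptic and
    postsynaptic evidence, post-processing of probability maps into synapse
    locations and per-channel Gaussian punctum descriptors, a synthetic
    multiplexed-scene simulator with ground truth, detection metrics
    (precision/recall/F1, pixel AUC, counting error) with greedy point
    matching, channel harmonization for cross-dataset transfer, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
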