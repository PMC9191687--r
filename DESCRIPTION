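Package: scavox
Title: Attention-Based 3D Patch-Wise Segmentation of White-Matter Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based volumetric segmentation of multiple-sclerosis
    white-matter lesions from FLAIR (optionally FLAIR + T1-weighted) MRI.
    Implements the full pipeline: CLAHE contrast enhancement and Laplacian
    edge channels, lesion-biased 3D patch sampling, a residual volumetric
    network with spatial-channel attention (SCA-VoxRes), Focal Tversky
    training with Adam and exponential learning-rate decay, tiled
    whole-volume inference with stitching, and lesion-wise evaluation
    (DSC, LTPR, LFPR, AVD over 18-connected components). Includes a
    synthetic brain-phantom generator with two disagreeing rater masks so
    the whole pipeline is testable without any external dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    tibble,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
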