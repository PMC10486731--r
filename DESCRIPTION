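Package: octafusion
Title: Hybrid Multimodal Fusion of 3D OCTA Volumes for Diabetic
    Retinopathy Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for grading diabetic retinopathy severity from paired
    three-dimensional optical coherence tomography angiography (OCTA)
    acquisitions. Provides a seeded synthetic cohort generator with
    curved retinal surfaces and severity-dependent lesions, retinal-band
    preprocessing (ILM/RPE surface segmentation, flattening, resizing and
    four cropping strategies), compact trainable 3D convolutional
    backbones (residual, densely connected and mobile inverted
    bottleneck families) built on an embedded reverse-mode autodiff
    engine, single-acquisition fusion of structure and flow channels at
    the input, feature, decision and hierarchical levels,
    cross-acquisition fusion, N-times random-crop inference with
    severest-prediction aggregation, and an ordinal/binary evaluation
    suite (cumulative-task AUC, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
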