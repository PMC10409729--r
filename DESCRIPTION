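Package: SliceVolReg
Title: Unsupervised Slice-to-Volume Rigid Registration of 3D CT to 2D
    Ultrasound Kidney Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step deep registration of a 3D CT kidney volume to 2D
    ultrasound frame sequences acquired during free breathing. Provides
    rigid-transform algebra with a differentiable spatial-transformer
    resampler, residual U-Net feature networks with local binary
    convolution skip layers producing kidney probability maps, a
    hierarchical encoder-decoder registration network regressing windowed
    rigid transforms at multiple scales, the feature-image-motion (FIM)
    composite loss built on the modality-independent neighbourhood
    descriptor (MIND), truncated-Gaussian training-pair generation with
    unsupervised pretraining and one-cycle transfer learning, synthetic
    breathing phantoms with ground-truth per-frame poses, and
    contour-distance evaluation metrics (Hausdorff and mean contour
    distance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
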