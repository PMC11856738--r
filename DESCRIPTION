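Package: mcmunet
Title: Multi-Scale Context Modeling U-Net for Prostate MRI Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder segmentation toolkit for T2-weighted prostate
    MRI built around two architectural extensions of the nnU-Net backbone: a
    context-modeling attention block attached to each decoder skip connection,
    which re-weights per-pixel features by their similarity to class-region
    representations derived from deep-supervision probability maps, and a
    fixed-capacity first-in-first-out memory bank that injects dataset-level
    semantic features into the deepest stage of the network. The package
    provides the full surrounding workflow: NIfTI volume input/output,
    resampling and Z-score normalization, 2D slice and 3D patch extraction, a
    synthetic prostate-phantom generator with apex/base boundary blurring,
    a compound Dice plus cross-entropy training objective with deep
    supervision, SGD training with Nesterov momentum and a polynomial
    learning-rate schedule, and surface-distance (ASSD, HD95) and overlap
    (Jaccard, Dice) evaluation metrics with per-case and aggregate reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    EBImage,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
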