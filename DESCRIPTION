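Package: pqseg
Title: Diffusion Tensor Decomposition and Multi-Scale CNN Segmentation of Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise diffusion-tensor fitting from multi-b-value
    diffusion-weighted MRI and decomposition into the isotropic (p) and
    anisotropic (q) maps alongside FA, MD and ADC; a synthetic multi-sequence
    glioblastoma phantom generator with nested tumor compartments and Rician
    noise; a dual-pathway multi-scale residual 3-D convolutional network for
    per-compartment segmentation over configurable channel combinations; and
    an evaluation layer with Dice scoring, majority-vote observer consensus,
    exact Wilcoxon signed-rank model comparison and a reproducible
    train/validate/test experiment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
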