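Package: coroflow
Title: Functional Significance of Coronary Stenosis from CCTA Centerline Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for assessing the functional significance of
    coronary artery stenosis (invasive fractional flow reserve, FFR, at or
    below 0.8) from coronary CT angiography. Provides straightened
    multiplanar reformation (MPR) along labeled artery centerlines with
    rotation-minimizing frames and trilinear interpolation; a 2D
    convolutional network that regresses per-cross-section lumen area, mean
    lumen attenuation and calcium area; bifurcation and main-branch
    characteristics from the centerline tree; a 1D convolutional network
    with a transformer layer whose regression head sums non-negative
    pressure drops into an FFR estimate and whose classification head
    predicts significance; pseudo-probability merging of the two heads;
    10-fold cross-validation ensembling with predictive uncertainty; and
    evaluation utilities (Mann-Whitney AUC, patient-level aggregation,
    paired AUC permutation testing, uncertainty-based referral simulation,
    characteristic-ablation harness). A synthetic vessel-phantom cohort
    generator with an analytic Poiseuille-type FFR model makes every stage
    trainable and testable without clinical data. The convolutional and
    transformer layers, backpropagation and the AdamW optimizer are
    implemented in the package (RcppArmadillo for the 2D operations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
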