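Package: aviatract
Title: Diffusion MRI Tractography and Population Fiber-Bundle Atlasing for Small Animal Brains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An ex vivo diffusion-MRI structural-connectivity pipeline for
    small animal (avian) brains. Provides multi-tensor synthetic DWI phantom
    generation, Rician-adapted non-local means denoising, DTI and analytical
    Q-ball (spherical harmonic) local modeling with scalar maps (ADC, FA,
    AD, RD, GFA), streamline-regularized deterministic tractography, and a
    two-level unsupervised fiber clustering scheme (intra-subject parcel
    connectivity clustering, inter-subject HDBSCAN centroid clustering)
    producing a labeled population bundle atlas with group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
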