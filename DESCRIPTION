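Package: nucleovol
Title: 3D Cyto-Nuclear and Nucleolar Foci Quantification for High-Content
    Fluorescence Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipelines for high-content confocal z-stacks of
    cultured neurons: per-slice nuclear segmentation from a DAPI channel,
    nearest-neighbour linking of 2D components into 3D nuclei, detection of
    bright nucleolar foci and their registration to host nuclei, cytoplasmic
    shell quantification, per-well aggregation, a normality-gated two-sample
    testing layer with Bonferroni correction, and delta-delta-Ct relative
    qPCR quantification with dual reference genes. Includes a synthetic
    phantom generator that renders multi-channel stacks with known ground
    truth (ellipsoidal nuclei, planted foci, Poisson-Gaussian noise) so every
    stage of the analysis can be verified without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
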