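Package: dynqsm
Title: Dynamic Quantitative Susceptibility Mapping for Contrast-Agent
    Concentration and Steady-State Cerebral Blood Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating gadolinium contrast-agent concentration and
    steady-state cerebral blood volume (CBV) from dynamic susceptibility
    contrast MRI phase data.  Provides a digital head phantom with a
    dipole-convolution forward model for dynamic gradient-echo magnitude and
    phase series; quality-guided phase unwrapping; projection-onto-dipole-field
    background removal; thresholded k-space division and morphology-enabled
    regularized dipole inversion; criteria-based selection of ventricular CSF
    reference pixels used to anchor the arbitrary offset of susceptibility
    maps over time; steady-state CBV estimation from tissue and blood
    susceptibility differences (and the Delta-R2* analogue); in vivo tissue
    relaxivity estimation; and test-retest repeatability analyses (ICC,
    Bland-Altman, threshold and regularization sweeps, age regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
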