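Package: couplemap
Title: Structure-Function Coupling, Heritability and Gradient Analysis of
    Cortical Connectomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the correspondence between cortical
    microstructure and intrinsic function at the level of brain parcels.
    Implements microstructure profile covariance (MPC) from equivolumetric
    depth-wise intensity profiles, Fisher-z resting-state functional
    connectivity, node-wise structure-function coupling, twin-based AE
    maximum-likelihood heritability of connectivity phenotypes, diffusion-map
    connectome gradients with Procrustes alignment and gradient-difference
    maps, spherical spin-test permutation nulls, and a two-dimensional
    quadrant/term-decoding model. Ships a synthetic-cohort generator with
    known ground truth so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
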