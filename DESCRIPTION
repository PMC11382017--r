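Package: lspheno
Title: Latent-Space Phenotyping of Plot-Level Canopy Imagery with Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Field Phenomics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for latent-space phenotyping of row-crop field trials from
    plot-level RGB imagery and digital surface models (DSMs). Provides a
    synthetic field/genotype generator with a controllable additive genetic
    architecture, VDVI-based vegetation segmentation and geometric
    standardization, a small multi-output convolutional network (built on
    compiled RcppArmadillo kernels) that maps plot imagery to a 30-dimensional
    latent feature vector and five biomass traits through a linear head, PCA of
    the latent features with rotation of the head weights into the principal
    component basis, GBLUP genomic prediction with REML variance components,
    and prediction of trait phenotypes from genomically predicted principal
    component scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
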