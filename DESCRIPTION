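Package: GradIQ
Title: Structural Connectome Gradients and Graph-Convolutional Prediction of Cognitive Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying macroscale gradients of the infant structural
    connectome and their relationship to later cognitive outcome. Implements
    streamline-count connectome validation and normalization, cosine-affinity
    diffusion-map gradient embedding with Procrustes alignment to a reference
    template, empirical-Bayes (ComBat) scanner harmonization with covariate
    protection, a Chebyshev spectral graph-convolutional regressor trained with
    a paired inter-subject (Siamese) loss, repeated k-fold cross-validation
    with permutation significance, gradient-based regional relevance maps
    (saliency and integrated gradients), and a synthetic cohort generator that
    emulates the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
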