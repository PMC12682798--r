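#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib GradIQ, .registration = TRUE
NULL

#' Parcellation metadata
#'
#' Ordered region table for a cortical parcellation: region identifiers,
#' hemisphere membership and display names. The row order defines the row
#' and column order of every connectome matrix built against it.
#'
#' @slot regionIds character vector of unique region identifiers.
#' @slot hemisphere character vector, one of \code{"L"} or \code{"R"} per region.
#' @slot displayName character vector of human-readable names.
#' @export
setClass("Parcellation",
  representation(regionIds = "character", hemisphere = "character",
                 displayName = "character"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@regionIds)
    if (length(object@hemisphere) != n || length(object@displayName) != n)
      msg <- c(msg, "regionIds, hemisphere and displayName must have equal length")
    if (anyDuplicated(object@regionIds))
      msg <- c(msg, "region ids must be unique")
    if (!all(object@hemisphere %in% c("L", "R")))
      msg <- c(msg, "hemisphere labels must be 'L' or 'R'")
    if (is.null(msg)) TRUE else msg
  })

#' Structural connectome matrix
#'
#' A square, symmetric, nonnegative region-by-region connectivity matrix
#' (streamline counts or normalized weights) tied to a \linkS4class{Parcellation}.
#' When \code{normalized} is \code{TRUE} the strictly-lower-triangular entries
#' sum to 1.
#'
#' @slot values numeric N x N matrix.
#' @slot parcellation a \linkS4class{Parcellation} with N regions.
#' @slot subjectId character scalar.
#' @slot normalized logical scalar.
#' @export
setClass("Connectome",
  representation(values = "matrix", parcellation = "Parcellation",
                 subjectId = "character", normalized = "logical"),
  validity = function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (nrow(v) != length(object@parcellation@regionIds))
      msg <- c(msg, "matrix dimension must match the parcellation")
    if (any(!is.finite(v))) msg <- c(msg, "entries must be finite")
    else {
      if (any(v < 0)) msg <- c(msg, "entries must be nonnegative")
      if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "matrix must be symmetric within 1e-10")
      if (isTRUE(object@normalized) &&
          abs(sum(v[lower.tri(v)]) - 1) > 1e-9)
        msg <- c(msg, "normalized connectome must have lower-triangular sum 1 within 1e-9")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Diffusion-map gradient set
#'
#' Per-subject embedding of a connectome: one column per gradient (column 1 is
#' the principal gradient), the matching eigenvalues sorted in decreasing
#' order, and each eigenvalue's share of the retained non-trivial eigenvalue
#' mass (the explanation ratio).
#'
#' @slot vectors numeric N x m matrix; rownames are region ids.
#' @slot eigenvalues numeric vector of length m, decreasing.
#' @slot explanationRatio numeric vector of length m summing to at most 1.
#' @slot aligned logical; \code{TRUE} after Procrustes alignment.
#' @export
setClass("GradientSet",
  representation(vectors = "matrix", eigenvalues = "numeric",
                 explanationRatio = "numeric", aligned = "logical"),
  validity = function(object) {
    msg <- NULL
    m <- ncol(object@vectors)
    if (length(object@eigenvalues) != m)
      msg <- c(msg, "one eigenvalue per gradient column required")
    if (length(object@explanationRatio) != m)
      msg <- c(msg, "one explanation ratio per gradient column required")
    if (m > 1 && any(diff(object@eigenvalues) > 1e-12))
      msg <- c(msg, "eigenvalues must be sorted in decreasing order")
    if (is.null(msg)) TRUE else msg
  })

#' Gradient reference template
#'
#' Group-level gradient basis built from an independent subject set by
#' generalized Procrustes analysis; every subject is aligned to it so that
#' gradient axes are comparable across subjects.
#'
#' @slot vectors numeric N x m matrix.
#' @slot provenance character vector of subject ids used to build it.
#' @export
setClass("GradientTemplate",
  representation(vectors = "matrix", provenance = "character"),
  validity = function(object) {
    norms <- sqrt(colSums(object@vectors^2))
    if (any(norms <= 0)) "template columns must have positive norm" else TRUE
  })

#' Fitted ComBat harmonization model
#'
#' Location/scale batch-effect model with parametric empirical-Bayes
#' shrinkage, storing everything needed to adjust held-out subjects of
#' already-seen batches.
#'
#' @slot batches character vector of batch levels seen at fit time.
#' @slot nPerBatch integer vector of per-batch sample sizes.
#' @slot alpha numeric vector: grand mean per feature.
#' @slot betaCov numeric matrix (covariates x features) of protected covariate
#'   coefficients; zero rows when no covariates were supplied.
#' @slot sigma numeric vector: pooled residual SD per feature.
#' @slot gammaStar numeric matrix (batches x features): shrunken location effects.
#' @slot deltaStar numeric matrix (batches x features): shrunken scale effects (SD units).
#' @slot covariateNames character vector.
#' @export
setClass("CombatModel",
  representation(batches = "character", nPerBatch = "integer",
                 alpha = "numeric", betaCov = "matrix", sigma = "numeric",
                 gammaStar = "matrix", deltaStar = "matrix",
                 covariateNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@batches) < 2) msg <- c(msg, "at least two batches required")
    if (any(object@deltaStar <= 0)) msg <- c(msg, "shrunken scale effects must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Graph operator for spectral convolution
#'
#' Symmetric normalized graph Laplacian of a connectome adjacency, its largest
#' eigenvalue, and the rescaled Laplacian whose spectrum lies in [-1, 1] as
#' required by Chebyshev polynomial filtering.
#'
#' @slot adjacency numeric N x N symmetric nonnegative matrix.
#' @slot degree numeric vector of row sums.
#' @slot laplacian numeric N x N matrix \eqn{L = I - D^{-1/2} A D^{-1/2}}.
#' @slot scaledLaplacian numeric N x N matrix \eqn{2L/\lambda_{max} - I}.
#' @slot lambdaMax numeric scalar, largest eigenvalue of \code{laplacian}.
#' @export
setClass("GraphOperator",
  representation(adjacency = "matrix", degree = "numeric", laplacian = "matrix",
                 scaledLaplacian = "matrix", lambdaMax = "numeric"))

#' Trained Chebyshev spectral GCN regressor
#'
#' Opaque trainable state of the graph-convolutional regression model:
#' per-layer Chebyshev coefficient matrices, readout (MLP) weights and biases,
#' the configuration used, and the training loss trajectory.
#'
#' @slot params list with elements \code{Wg} (GCN layer weights), \code{Wm}
#'   and \code{bm} (MLP weights and biases).
#' @slot config list as returned by \code{\link{gcnConfig}}.
#' @slot epochLoss numeric vector: total training loss per epoch.
#' @slot hemisphere character vector of per-region hemisphere labels of the
#'   training inputs (needed to normalize new inputs identically).
#' @export
setClass("GCNModel",
  representation(params = "list", config = "list", epochLoss = "numeric",
                 hemisphere = "character"))

#' Synthetic connectome cohort
#'
#' A fully simulated cohort carrying everything the analysis pipeline
#' consumes: normalized connectomes, template-aligned gradient features (with
#' planted scanner batch effects), covariates, batch labels and IQ-like
#' outcome scores, plus a ground-truth record used only by recovery tests.
#'
#' @slot connectomes list of \linkS4class{Connectome} objects (analysis subjects).
#' @slot features numeric array N x d x n of aligned gradient features.
#' @slot iq numeric matrix n x nScores of outcome scores.
#' @slot batch factor of scanner batch labels.
#' @slot covariates data.frame of per-subject covariates.
#' @slot template the \linkS4class{GradientTemplate} used for alignment.
#' @slot parcellation the \linkS4class{Parcellation}.
#' @slot groundTruth list: planted relevant regions, effect size, signal and
#'   clean (pre-batch-effect) features. Never consumed by the pipeline.
#' @slot config the \code{\link{simulationConfig}} list used.
#' @export
setClass("SyntheticCohort",
  representation(connectomes = "list", features = "array", iq = "matrix",
                 batch = "factor", covariates = "data.frame",
                 template = "GradientTemplate", parcellation = "Parcellation",
                 groundTruth = "list", config = "list"))

#' Regional relevance map
#'
#' Per-region attribution weights from a trained model, with the attribution
#' method, the per-component weights before summing, and a record of how many
#' subjects/models were averaged.
#'
#' @slot weights numeric vector, one weight per region (named by region id).
#' @slot componentWeights numeric N x d matrix of per-component weights.
#' @slot method character: \code{"saliency"} or \code{"integrated_gradients"}.
#' @slot mode character: \code{"magnitude"} or \code{"signed"} aggregation.
#' @slot provenance list describing what was averaged.
#' @export
setClass("RelevanceMap",
  representation(weights = "numeric", componentWeights = "matrix",
                 method = "character", mode = "character", provenance = "list"),
  validity = function(object) {
    if (any(!is.finite(object@weights))) "weights must be finite" else TRUE
  })
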