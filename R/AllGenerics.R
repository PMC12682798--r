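#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))
#' @rdname accessors
#' @export
setGeneric("parcellation", function(x) standardGeneric("parcellation"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))
#' @rdname accessors
#' @export
setGeneric("gradientVectors", function(x) standardGeneric("gradientVectors"))
#' @rdname accessors
#' @export
setGeneric("gradientEigenvalues", function(x) standardGeneric("gradientEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("explanationRatio", function(x) standardGeneric("explanationRatio"))
#' @rdname accessors
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))
#' @rdname accessors
#' @export
setGeneric("relevanceWeights", function(x) standardGeneric("relevanceWeights"))

#' Symmetrize a streamline-count matrix
#'
#' Raw tractography count matrices are direction-dependent; downstream
#' gradient analysis assumes an undirected network, so counts are symmetrized
#' first. The default rule is the arithmetic mean of the matrix and its
#' transpose; \code{method = "sum"} uses the sum instead.
#'
#' @param x a square nonnegative numeric matrix or a \linkS4class{Connectome}.
#' @param method \code{"mean"} (default) or \code{"sum"}.
#' @return an object of the same kind as \code{x}, exactly symmetric.
#' @export
setGeneric("symmetrizeConnectome",
           function(x, method = c("mean", "sum")) standardGeneric("symmetrizeConnectome"))

#' Normalize a connectome to unit lower-triangular mass
#'
#' Divides every entry by the sum of the strictly-lower-triangular entries so
#' that subjects with different total streamline counts become comparable;
#' after normalization that sum equals 1.
#'
#' @param x a symmetric nonnegative matrix or \linkS4class{Connectome} with at
#'   least one positive off-diagonal entry.
#' @return an object of the same kind as \code{x}, with the
#'   \code{normalized} flag set when \code{x} is a \linkS4class{Connectome}.
#' @export
setGeneric("normalizeConnectome", function(x) standardGeneric("normalizeConnectome"))
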