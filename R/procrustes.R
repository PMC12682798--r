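#' Orthogonal Procrustes alignment of gradients to a template
#'
#' Finds the orthogonal matrix R (rotation or rotation+reflection, no scaling
#' or translation) minimizing \eqn{\|S R - T\|_F} between the source gradient
#' matrix S and the template T, via the SVD of \eqn{S^\top T}. Orthogonality
#' means within-subject pairwise distances between regions are preserved
#' exactly; only the arbitrary axes of the embedding change.
#'
#' @param source a \linkS4class{GradientSet} (or numeric matrix).
#' @param template a \linkS4class{GradientTemplate} (or numeric matrix) with
#'   the same dimensions.
#' @return list with \code{aligned} (same class as \code{source}, aligned
#'   flag set) and \code{rotation} (the m x m orthogonal matrix).
#' @export
procrustesAlign <- function(source, template) {
  sv <- if (is(source, "GradientSet")) source@vectors else as.matrix(source)
  tv <- if (is(template, "GradientTemplate")) template@vectors else as.matrix(template)
  if (!all(dim(sv) == dim(tv)))
    stop("source and template must have identical dimensions")
  sv_dec <- svd(crossprod(sv, tv))
  rot <- sv_dec$u %*% t(sv_dec$v)
  aligned_mat <- sv %*% rot
  rownames(aligned_mat) <- rownames(sv)
  if (is(source, "GradientSet")) {
    aligned <- new("GradientSet", vectors = aligned_mat,
                   eigenvalues = source@eigenvalues,
                   explanationRatio = source@explanationRatio, aligned = TRUE)
  } else aligned <- aligned_mat
  list(aligned = aligned, rotation = rot)
}

#' Build a gradient reference template by generalized Procrustes analysis
#'
#' Initializes the template as the first subject's gradients, then iterates
#' (align every subject to the template; replace the template by the
#' element-wise mean of the aligned sets) until the template changes by less
#' than \code{tol} in Frobenius norm or \code{maxIter} is reached. On
#' non-convergence the best iterate is returned with a warning. The sign of
#' each template column is fixed so its largest-magnitude entry is positive;
#' subjects inherit signs through alignment.
#'
#' @param gradientSets list of \linkS4class{GradientSet} objects of equal
#'   shape (at least 2).
#' @param tol convergence tolerance on the template change; default 1e-8.
#' @param maxIter maximum iterations; default 500 (the iteration converges
#'   linearly, so a few hundred steps are routinely needed).
#' @param subjectIds optional character vector recorded as provenance.
#' @return a \linkS4class{GradientTemplate}.
#' @export
buildTemplate <- function(gradientSets, tol = 1e-8, maxIter = 500,
                          subjectIds = NULL) {
  if (length(gradientSets) < 2) stop("at least two gradient sets required")
  mats <- lapply(gradientSets, function(g)
    if (is(g, "GradientSet")) g@vectors else as.matrix(g))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all gradient sets must have identical shapes")
  template <- mats[[1L]]
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    aligned <- lapply(mats, function(m) procrustesAlign(m, template)$aligned)
    newt <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(sum((newt - template)^2))
    template <- newt
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("template did not converge in %d iterations; returning best iterate",
                    maxIter))
  for (j in seq_len(ncol(template))) {
    i <- which.max(abs(template[, j]))
    if (template[i, j] < 0) template[, j] <- -template[, j]
  }
  rownames(template) <- rownames(mats[[1L]])
  if (is.null(subjectIds)) subjectIds <- paste0("subject", seq_along(mats))
  new("GradientTemplate", vectors = template, provenance = subjectIds)
}
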