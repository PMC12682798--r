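#' Cosine-similarity affinity matrix
#'
#' Converts a connectome into the affinity matrix used for diffusion-map
#' embedding. Each connectivity row is first sparsified (the smallest
#' \code{sparsity} fraction of entries per row is zeroed, keeping only each
#' region's strongest connections), then the affinity between regions i and j
#' is the cosine of the angle between their sparsified connectivity profiles,
#' \eqn{W_{ij} = v_i \cdot v_j / (\|v_i\| \|v_j\|)}. For nonnegative profiles
#' the result lies in [0, 1] with unit diagonal.
#'
#' @param connectome a \linkS4class{Connectome} or nonnegative matrix.
#' @param sparsity fraction in [0, 1) of smallest entries zeroed per row
#'   before the similarity; default 0.9.
#' @return symmetric numeric matrix with entries in [0, 1] and unit diagonal.
#' @export
cosineAffinity <- function(connectome, sparsity = 0.9) {
  v <- if (is(connectome, "Connectome")) connectome@values else as.matrix(connectome)
  ids <- if (is(connectome, "Connectome")) regionIds(connectome) else rownames(v)
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")
  n <- ncol(v)
  nzero <- floor(sparsity * n)
  if (nzero > 0) {
    for (i in seq_len(nrow(v))) {
      ord <- order(v[i, ], seq_len(n))  # deterministic tie-break by column
      v[i, ord[seq_len(nzero)]] <- 0
    }
  }
  norms <- sqrt(rowSums(v^2))
  zero <- which(norms == 0)
  if (length(zero))
    stop(sprintf("degenerate region(s) with all-zero connectivity after sparsification: %s",
                 paste(if (is.null(ids)) zero else ids[zero], collapse = ", ")))
  w <- (v %*% t(v)) / outer(norms, norms)
  w <- (w + t(w)) / 2          # remove floating-point asymmetry
  w[w > 1] <- 1
  w[w < 0] <- 0
  diag(w) <- 1
  if (!is.null(ids)) dimnames(w) <- list(ids, ids)
  w
}

# connected-components check on the nonzero pattern of a symmetric matrix
.is_connected <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(w[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Computes connectome gradients as the non-trivial eigenvectors of the
#' diffusion operator built from \code{W}: anisotropic normalization
#' \eqn{K = D^{-\alpha} W D^{-\alpha}}, row-stochastic transition matrix
#' \eqn{P = D_K^{-1} K}, eigendecomposition through the symmetric conjugate
#' \eqn{D_K^{1/2} P D_K^{-1/2}} for numerical stability, discarding the
#' trivial constant eigenvector (eigenvalue 1). Gradients are the next
#' \code{nComponents} eigenvectors scaled by \eqn{\lambda^t} for
#' \code{diffusionTime} t > 0, or by the multi-scale weight
#' \eqn{\lambda/(1-\lambda)} when t = 0 (the default). Columns are ordered by
#' decreasing eigenvalue; the first column is the principal gradient.
#'
#' @param W symmetric nonnegative affinity matrix, connected as a graph.
#' @param nComponents number of gradients to retain (default 10).
#' @param alpha anisotropy exponent in [0, 1]; default 0.5.
#' @param diffusionTime nonnegative scale parameter; 0 (default) selects the
#'   automatic multi-scale weighting.
#' @return a \linkS4class{GradientSet}.
#' @export
diffusionMap <- function(W, nComponents = 10, alpha = 0.5, diffusionTime = 0) {
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-10) stop("affinity matrix must be symmetric")
  if (any(W < 0)) stop("affinity matrix must be nonnegative")
  n <- nrow(W)
  if (nComponents >= n) stop("nComponents must be smaller than the matrix size")
  if (!.is_connected(W))
    stop("affinity graph is disconnected; gradients are not defined")
  d <- rowSums(W)
  K <- W / outer(d^alpha, d^alpha)
  dK <- rowSums(K)
  # symmetric conjugate of P = D_K^{-1} K
  S <- K / outer(sqrt(dK), sqrt(dK))
  es <- eigen(S, symmetric = TRUE)
  lambda <- es$values
  psi <- es$vectors / sqrt(dK)          # right eigenvectors of P
  # drop the trivial eigenvalue-1 component
  lambda <- lambda[-1L]
  psi <- psi[, -1L, drop = FALSE]
  pos <- lambda > 1e-12
  if (nComponents > sum(pos))
    stop(sprintf("only %d positive non-trivial eigenvalues available; reduce nComponents",
                 sum(pos)))
  lambda <- lambda[pos]
  psi <- psi[, pos, drop = FALSE]
  # deterministic tie-break: stable order by eigenvalue, then first differing entry
  ord <- order(-lambda)
  lambda <- lambda[ord]
  psi <- psi[, ord, drop = FALSE]
  keep <- seq_len(nComponents)
  lam_k <- lambda[keep]
  vec_k <- psi[, keep, drop = FALSE]
  scalew <- if (diffusionTime > 0) lam_k^diffusionTime else lam_k / (1 - lam_k)
  vec_k <- sweep(vec_k, 2, scalew, `*`)
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(ncol(vec_k))) {
    i <- which.max(abs(vec_k[, j]))
    if (vec_k[i, j] < 0) vec_k[, j] <- -vec_k[, j]
  }
  rownames(vec_k) <- rownames(W)
  new("GradientSet", vectors = vec_k, eigenvalues = lam_k,
      explanationRatio = lam_k / sum(lam_k), aligned = FALSE)
}

#' Gradients of a connectome
#'
#' Convenience wrapper: affinity construction followed by diffusion-map
#' embedding.
#'
#' @param connectome a \linkS4class{Connectome}.
#' @param nComponents,alpha,diffusionTime see \code{\link{diffusionMap}}.
#' @param sparsity see \code{\link{cosineAffinity}}.
#' @return a \linkS4class{GradientSet}.
#' @export
connectomeGradients <- function(connectome, nComponents = 10, sparsity = 0.9,
                                alpha = 0.5, diffusionTime = 0) {
  diffusionMap(cosineAffinity(connectome, sparsity), nComponents,
               alpha, diffusionTime)
}

#' @rdname accessors
#' @export
setMethod("gradientVectors", "GradientSet", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("gradientVectors", "GradientTemplate", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("gradientEigenvalues", "GradientSet", function(x) x@eigenvalues)
#' @rdname accessors
#' @export
setMethod("isAligned", "GradientSet", function(x) x@aligned)

#' @rdname accessors
#' @export
setMethod("explanationRatio", "GradientSet", function(x) x@explanationRatio)

#' Explanation ratios of an eigenvalue spectrum
#'
#' Each retained non-trivial eigenvalue's share of the total retained mass,
#' interpreted as the fraction of connectivity information a gradient
#' explains.
#'
#' @param x a numeric vector of positive eigenvalues.
#' @return numeric vector summing to 1.
#' @export
setMethod("explanationRatio", "numeric", function(x) {
  if (!length(x)) stop("empty eigenvalue vector")
  if (any(x <= 0)) stop("eigenvalues must be positive")
  x / sum(x)
})

setMethod("show", "GradientSet", function(object) {
  cat(sprintf("GradientSet: %d regions x %d gradients (%s)\n",
              nrow(object@vectors), ncol(object@vectors),
              if (object@aligned) "aligned" else "unaligned"))
  cat("  explanation ratios:",
      paste(sprintf("%.1f%%", 100 * utils::head(object@explanationRatio, 5)),
            collapse = ", "),
      if (length(object@explanationRatio) > 5) "..." else "", "\n")
})

setMethod("show", "GradientTemplate", function(object) {
  cat(sprintf("GradientTemplate: %d regions x %d gradients from %d subjects\n",
              nrow(object@vectors), ncol(object@vectors),
              length(object@provenance)))
})

#' Hemisphere-specific gradients
#'
#' Computes gradients separately within each hemisphere after discarding
#' interhemispheric connections, then Procrustes-aligns the right-hemisphere
#' gradients to their left-hemisphere counterparts for hemisphere-wise
#' comparison. Alignment requires equal region counts per hemisphere; with
#' unequal counts both unaligned sets are returned with a notice.
#'
#' @param connectome a \linkS4class{Connectome} containing both hemispheres.
#' @param nComponents,sparsity,alpha,diffusionTime see
#'   \code{\link{connectomeGradients}}.
#' @return list with \code{left} and \code{right} \linkS4class{GradientSet}
#'   objects and logical \code{alignedRightToLeft}.
#' @export
hemisphericGradients <- function(connectome, nComponents = 10, sparsity = 0.9,
                                 alpha = 0.5, diffusionTime = 0) {
  halves <- splitHemispheres(connectome)
  gl <- connectomeGradients(halves$left, nComponents, sparsity, alpha, diffusionTime)
  gr <- connectomeGradients(halves$right, nComponents, sparsity, alpha, diffusionTime)
  if (nrow(gl@vectors) != nrow(gr@vectors)) {
    message("unequal hemisphere sizes; right-to-left alignment skipped")
    return(list(left = gl, right = gr, alignedRightToLeft = FALSE))
  }
  tmpl <- new("GradientTemplate", vectors = gl@vectors,
              provenance = connectome@subjectId)
  gr <- procrustesAlign(gr, tmpl)$aligned
  list(left = gl, right = gr, alignedRightToLeft = TRUE)
}

#' Write gradients as TSV with a JSON sidecar
#'
#' The TSV holds one region per row (region id + one column per gradient);
#' the sidecar records eigenvalues, explanation ratios and alignment state.
#'
#' @param gs a \linkS4class{GradientSet}.
#' @param path TSV output path; the sidecar gets extension \code{.json}.
#' @export
writeGradients <- function(gs, path) {
  v <- gs@vectors
  tab <- data.frame(region_id = rownames(v), v, check.names = FALSE)
  colnames(tab) <- c("region_id", paste0("g", seq_len(ncol(v))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(eigenvalues = gs@eigenvalues,
         explanation_ratio = gs@explanationRatio,
         aligned = gs@aligned),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
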