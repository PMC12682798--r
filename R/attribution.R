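#' Saliency map of a trained GCN regressor
#'
#' Absolute gradient of the prediction with respect to each input feature,
#' \eqn{|\partial f(x) / \partial x|}, evaluated at each subject's input:
#' one weight per region and gradient component. Computed by the analytic
#' backward pass of the network.
#'
#' @param model a \linkS4class{GCNModel}.
#' @param adjacency list of per-subject adjacency matrices or
#'   \linkS4class{Connectome}s.
#' @param features list of per-subject N x d normalized feature matrices.
#' @param signed return the raw signed gradients instead of magnitudes;
#'   default FALSE.
#' @param graphBundles optional precomputed spectral bundles (see
#'   \code{\link{gcnForward}}).
#' @return list of N x d matrices, one per subject.
#' @export
saliencyMap <- function(model, adjacency, features, signed = FALSE,
                        graphBundles = NULL) {
  cfg <- model@config
  bundles <- .make_bundles(adjacency, features, cfg$K, graphBundles)
  g <- gcn_input_grad_cpp(bundles, model@params$Wg, model@params$Wm,
                          model@params$bm, cfg$K)
  if (signed) g else lapply(g, abs)
}

#' Integrated gradients attribution
#'
#' Path-integrated attribution along the straight line from a baseline b to
#' the input x: \eqn{IG_i = (x_i - b_i) \cdot \frac{1}{S}\sum_s \partial
#' f/\partial x_i} evaluated at the Riemann midpoints
#' \eqn{b + \frac{s - 1/2}{S}(x - b)}. Satisfies completeness: attributions
#' sum to \eqn{f(x) - f(b)} up to the Riemann discretization error, which
#' shrinks with \code{steps}. The default baseline is the all-zero feature
#' matrix, the natural origin for unitless embedding coordinates.
#'
#' @param model a \linkS4class{GCNModel}.
#' @param adjacency,features as in \code{\link{saliencyMap}}.
#' @param baseline a single N x d matrix used for every subject, or a list of
#'   per-subject matrices; default all zeros.
#' @param steps number of Riemann steps (>= 1); default 50.
#' @param graphBundles optional precomputed spectral bundles (see
#'   \code{\link{gcnForward}}).
#' @return list of signed N x d attribution matrices, one per subject.
#' @export
integratedGradientsMap <- function(model, adjacency, features, baseline = NULL,
                                   steps = 50, graphBundles = NULL) {
  if (steps < 1) stop("steps must be at least 1")
  cfg <- model@config
  n <- length(features)
  features <- lapply(features, as.matrix)
  if (is.null(baseline))
    baseline <- lapply(features, function(x) matrix(0, nrow(x), ncol(x)))
  else if (!is.list(baseline))
    baseline <- rep(list(as.matrix(baseline)), n)
  bundles <- .make_bundles(adjacency, features, cfg$K, graphBundles)
  acc <- lapply(features, function(x) matrix(0, nrow(x), ncol(x)))
  for (s in seq_len(steps)) {
    t_s <- (s - 0.5) / steps
    step_bundles <- lapply(seq_len(n), function(i)
      subjectWithFeatures(bundles[[i]],
                          baseline[[i]] + t_s * (features[[i]] - baseline[[i]]),
                          cfg$K))
    g <- gcn_input_grad_cpp(step_bundles, model@params$Wg, model@params$Wm,
                            model@params$bm, cfg$K)
    acc <- lapply(seq_len(n), function(i) acc[[i]] + g[[i]])
  }
  lapply(seq_len(n), function(i)
    (features[[i]] - baseline[[i]]) * acc[[i]] / steps)
}

#' Aggregate per-subject relevance into a regional map
#'
#' Averages attribution matrices across subjects (and across folds or
#' repetitions when maps from several models are pooled). In
#' \code{"magnitude"} mode (the default) absolute values are taken before
#' averaging and components are summed afterwards, reflecting that the sign
#' of embedding-coordinate attributions is not interpretable; \code{"signed"}
#' mode averages raw values.
#'
#' @param maps list of N x d attribution matrices with identical shapes, or a
#'   list of such lists (e.g. one per fold).
#' @param regionIds character vector of region ids, length N.
#' @param method attribution method tag stored on the result.
#' @param mode \code{"magnitude"} (default) or \code{"signed"}.
#' @return a \linkS4class{RelevanceMap}.
#' @export
aggregateRelevance <- function(maps, regionIds,
                               method = c("saliency", "integrated_gradients"),
                               mode = c("magnitude", "signed")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (is.list(maps[[1]])) maps <- unlist(maps, recursive = FALSE)
  dims <- vapply(maps, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all maps must have identical region sets")
  if (length(regionIds) != dims[1, 1])
    stop("regionIds length must match the maps")
  if (mode == "magnitude") maps <- lapply(maps, abs)
  comp <- Reduce(`+`, maps) / length(maps)
  w <- rowSums(comp)
  names(w) <- regionIds
  rownames(comp) <- regionIds
  new("RelevanceMap", weights = w, componentWeights = comp, method = method,
      mode = mode, provenance = list(nMaps = length(maps)))
}

#' @rdname accessors
#' @export
setMethod("relevanceWeights", "RelevanceMap", function(x) x@weights)

setMethod("show", "RelevanceMap", function(object) {
  cat(sprintf("RelevanceMap (%s, %s): %d regions, averaged over %d maps\n",
              object@method, object@mode, length(object@weights),
              object@provenance$nMaps))
  top <- utils::head(sort(object@weights, decreasing = TRUE), 3)
  cat("  top regions:", paste(sprintf("%s (%.3g)", names(top), top),
                              collapse = ", "), "\n")
})

#' Top-fraction region selection
#'
#' The \code{ceiling(fraction * N)} regions with the largest absolute
#' aggregated weight, ties broken deterministically by region id.
#'
#' @param map a \linkS4class{RelevanceMap} (or named numeric weight vector).
#' @param fraction fraction in (0, 1]; default 0.05.
#' @return character vector of region ids, ordered by decreasing weight.
#' @export
topFractionRegions <- function(map, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  w <- if (is(map, "RelevanceMap")) map@weights else map
  k <- ceiling(fraction * length(w))
  ord <- order(-abs(w), names(w))
  names(w)[ord][seq_len(k)]
}

#' Regions consistently selected across target outcomes
#'
#' Intersection of top-region subsets computed for different target scores.
#'
#' @param subsets list of character vectors of region ids.
#' @return character vector (possibly empty).
#' @export
consistentRegions <- function(subsets) {
  Reduce(intersect, subsets)
}

#' Write a relevance map as TSV with JSON provenance
#'
#' @param map a \linkS4class{RelevanceMap}.
#' @param path TSV output path; provenance goes to a \code{.json} sidecar.
#' @param fraction top-fraction marker column; default 0.05.
#' @export
writeRelevanceMap <- function(map, path, fraction = 0.05) {
  top <- topFractionRegions(map, fraction)
  w <- map@weights
  tab <- data.frame(region_id = names(w), weight = w,
                    rank = rank(-abs(w), ties.method = "first"),
                    selected_top = names(w) %in% top)
  tab <- tab[order(tab$rank), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(map@provenance,
                         list(method = map@method, mode = map@mode,
                              fraction = fraction)),
                       sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
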