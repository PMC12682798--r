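#' Construct a Parcellation
#'
#' @param regionIds character vector of unique region ids.
#' @param hemisphere character vector of \code{"L"}/\code{"R"} labels.
#' @param displayName optional character vector of display names; defaults to
#'   \code{regionIds}.
#' @return a \linkS4class{Parcellation}.
#' @examples
#' p <- Parcellation(c("a", "b"), c("L", "R"))
#' @export
Parcellation <- function(regionIds, hemisphere, displayName = regionIds) {
  new("Parcellation", regionIds = as.character(regionIds),
      hemisphere = as.character(hemisphere),
      displayName = as.character(displayName))
}

#' Construct a Connectome
#'
#' Validates symmetry (within 1e-10), nonnegativity and agreement with the
#' parcellation. Diagonal (self-connection) entries are forced to zero:
#' tractography self-loops carry no meaning here and normalization concerns
#' strictly off-diagonal mass only.
#'
#' @param values numeric N x N matrix.
#' @param parcellation a \linkS4class{Parcellation} with N regions.
#' @param subjectId character scalar.
#' @param normalized logical; set by \code{\link{normalizeConnectome}}.
#' @return a \linkS4class{Connectome}.
#' @export
Connectome <- function(values, parcellation, subjectId = "subject",
                       normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) == ncol(values)) diag(values) <- 0
  dimnames(values) <- list(parcellation@regionIds, parcellation@regionIds)
  new("Connectome", values = values, parcellation = parcellation,
      subjectId = subjectId, normalized = normalized)
}

#' Read a parcellation table
#'
#' Expects a tab-separated file with columns \code{region_id},
#' \code{hemisphere} and optionally \code{display_name}.
#'
#' @param path file path.
#' @return a \linkS4class{Parcellation}.
#' @export
readParcellation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "hemisphere")
  if (!all(need %in% names(tab)))
    stop("parcellation table must contain columns region_id and hemisphere")
  dn <- if ("display_name" %in% names(tab)) tab$display_name else tab$region_id
  Parcellation(tab$region_id, tab$hemisphere, dn)
}

#' Write a parcellation table
#'
#' @param parcellation a \linkS4class{Parcellation}.
#' @param path file path.
#' @export
writeParcellation <- function(parcellation, path) {
  utils::write.table(
    data.frame(region_id = parcellation@regionIds,
               hemisphere = parcellation@hemisphere,
               display_name = parcellation@displayName),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense connectome matrix from delimited text
#'
#' Reads an N x N numeric matrix (comma- or tab-delimited, auto-detected) in
#' the row/column order of \code{parcellation}. No name-based reordering is
#' attempted: file row order must match the parcellation order.
#'
#' @param path file path.
#' @param parcellation a \linkS4class{Parcellation}; its size fixes N.
#' @param subjectId subject identifier stored on the result.
#' @param header logical; default \code{FALSE} (plain numeric matrix).
#' @return a validated \linkS4class{Connectome}.
#' @export
readConnectome <- function(path, parcellation, subjectId = basename(path),
                           header = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = header))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  n <- length(parcellation@regionIds)
  if (nrow(m) != n || ncol(m) != n)
    stop(sprintf("connectome is %d x %d but the parcellation has %d regions",
                 nrow(m), ncol(m), n))
  if (any(!is.finite(m)))
    stop("connectome contains non-finite entries")
  if (any(m < 0))
    stop("connectome contains negative entries")
  Connectome(m, parcellation, subjectId = subjectId)
}

#' Write a connectome matrix as delimited text
#'
#' @param connectome a \linkS4class{Connectome}.
#' @param path file path.
#' @param sep field separator, \code{","} (default) or \code{"\t"}.
#' @export
writeConnectome <- function(connectome, path, sep = ",") {
  utils::write.table(connectome@values, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname symmetrizeConnectome
#' @export
setMethod("symmetrizeConnectome", "matrix", function(x, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (nrow(x) != ncol(x)) stop("input must be a square matrix")
  if (any(x < 0)) stop("input must be nonnegative")
  s <- x + t(x)
  if (method == "mean") s <- s / 2
  s
})

#' @rdname symmetrizeConnectome
#' @export
setMethod("symmetrizeConnectome", "Connectome", function(x, method = c("mean", "sum")) {
  Connectome(symmetrizeConnectome(x@values, method), x@parcellation,
             subjectId = x@subjectId)
})

#' @rdname normalizeConnectome
#' @export
setMethod("normalizeConnectome", "matrix", function(x) {
  if (max(abs(x - t(x))) > 1e-10) stop("input must be symmetric")
  s <- sum(x[lower.tri(x)])
  if (s <= 0) stop("degenerate connectome: no positive off-diagonal entries")
  x / s
})

#' @rdname normalizeConnectome
#' @export
setMethod("normalizeConnectome", "Connectome", function(x) {
  Connectome(normalizeConnectome(x@values), x@parcellation,
             subjectId = x@subjectId, normalized = TRUE)
})

#' Split a connectome into hemisphere-specific submatrices
#'
#' Extracts the left-left and right-right principal submatrices, discarding
#' interhemispheric connections. Used for hemisphere-specific gradient
#' analysis, where interhemispheric edges are excluded by design.
#'
#' @param connectome a \linkS4class{Connectome} whose parcellation contains
#'   both hemispheres.
#' @return named list with \code{left} and \code{right}
#'   \linkS4class{Connectome} objects.
#' @export
splitHemispheres <- function(connectome) {
  hemi <- connectome@parcellation@hemisphere
  if (!all(c("L", "R") %in% hemi))
    stop("both hemispheres must be present in the parcellation")
  out <- lapply(c(L = "L", R = "R"), function(h) {
    idx <- which(hemi == h)
    p <- Parcellation(connectome@parcellation@regionIds[idx],
                      hemi[idx],
                      connectome@parcellation@displayName[idx])
    Connectome(connectome@values[idx, idx, drop = FALSE], p,
               subjectId = connectome@subjectId)
  })
  list(left = out$L, right = out$R)
}

## Accessors -----------------------------------------------------------------

#' Accessors for GradIQ classes
#'
#' @param x an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("connMatrix", "Connectome", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("parcellation", "Connectome", function(x) x@parcellation)
#' @rdname accessors
#' @export
setMethod("subjectId", "Connectome", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("isNormalized", "Connectome", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("regionIds", "Parcellation", function(x) x@regionIds)
#' @rdname accessors
#' @export
setMethod("regionIds", "Connectome", function(x) x@parcellation@regionIds)
#' @rdname accessors
#' @export
setMethod("hemispheres", "Parcellation", function(x) x@hemisphere)
#' @rdname accessors
#' @export
setMethod("hemispheres", "Connectome", function(x) x@parcellation@hemisphere)

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation with %d regions (%d L / %d R)\n",
              length(object@regionIds), sum(object@hemisphere == "L"),
              sum(object@hemisphere == "R")))
})

setMethod("show", "Connectome", function(object) {
  v <- object@values
  cat(sprintf("Connectome '%s': %d x %d, %s\n", object@subjectId, nrow(v),
              ncol(v), if (object@normalized) "normalized" else "raw counts"))
  cat(sprintf("  nonzero off-diagonal entries: %d; lower-triangular sum: %.6g\n",
              sum(v[lower.tri(v)] > 0) * 2L, sum(v[lower.tri(v)])))
})
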