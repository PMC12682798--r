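#' Fit a ComBat batch-harmonization model
#'
#' Empirical-Bayes location/scale harmonization of scanner batch effects.
#' Features are standardized by a covariate-adjusted grand mean and pooled
#' variance; per-batch location (gamma) and scale (delta squared) effects are
#' then shrunk toward parametric priors (normal for location, inverse-gamma
#' for scale) using the standard iterative conditional-posterior update.
#' Covariate effects are estimated jointly and protected: they are removed
#' before batch estimation and restored after adjustment.
#'
#' @param features numeric matrix, subjects x features.
#' @param batch factor (or coercible) of batch labels, at least 2 subjects in
#'   each of at least 2 batches.
#' @param covariates optional numeric data.frame/matrix (subjects x
#'   covariates); must be full rank together with the batch design.
#' @param tol convergence tolerance of the EB iteration; default 1e-4.
#' @param maxIter maximum EB iterations; default 100.
#' @return a \linkS4class{CombatModel}.
#' @references Johnson, Li & Rabinovic (2007) Biostatistics 8(1):118-127.
#' @export
combatFit <- function(features, batch, covariates = NULL,
                      tol = 1e-4, maxIter = 100) {
  Y <- as.matrix(features)
  batch <- droplevels(as.factor(batch))
  if (length(batch) != nrow(Y)) stop("one batch label per subject required")
  nb <- table(batch)
  if (length(nb) < 2) stop("at least two batches required")
  if (any(nb < 2)) stop(sprintf("singleton batch: %s",
                                paste(names(nb)[nb < 2], collapse = ", ")))
  B <- stats::model.matrix(~ batch - 1)
  if (!is.null(covariates)) {
    Xc <- as.matrix(as.data.frame(covariates))
    storage.mode(Xc) <- "double"
    if (is.null(colnames(Xc))) colnames(Xc) <- paste0("cov", seq_len(ncol(Xc)))
  } else Xc <- matrix(0, nrow(Y), 0)
  X <- cbind(B, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, Y)                      # (B + C) x F
  nbatch <- nlevels(batch)
  gammahat0 <- beta[seq_len(nbatch), , drop = FALSE]
  betaCov <- beta[-seq_len(nbatch), , drop = FALSE]
  n <- nrow(Y)
  alpha <- as.numeric(crossprod(nb / n, gammahat0))  # weighted grand mean
  fitted <- X %*% beta
  sigma2 <- colMeans((Y - fitted)^2)
  if (any(sigma2 <= 0)) stop("zero residual variance for some feature")
  sigma <- sqrt(sigma2)
  standMean <- matrix(alpha, n, ncol(Y), byrow = TRUE) +
    if (ncol(Xc)) Xc %*% betaCov else 0
  Z <- (Y - standMean) / matrix(sigma, n, ncol(Y), byrow = TRUE)

  gammaStar <- matrix(0, nbatch, ncol(Y))
  deltaStar <- matrix(1, nbatch, ncol(Y))
  for (b in seq_len(nbatch)) {
    idx <- which(batch == levels(batch)[b])
    Zb <- Z[idx, , drop = FALSE]
    ghat <- colMeans(Zb)
    d2hat <- apply(Zb, 2, stats::var)
    nB <- length(idx)
    if (ncol(Y) < 2) {
      # hyperpriors are moments across features; with a single feature there
      # is nothing to borrow strength from, so use the direct estimates
      gammaStar[b, ] <- ghat
      deltaStar[b, ] <- sqrt(d2hat)
      next
    }
    # parametric priors by method of moments
    gbar <- mean(ghat); t2 <- stats::var(ghat)
    m <- mean(d2hat); s2 <- stats::var(d2hat)
    aprior <- (2 * s2 + m^2) / s2
    bprior <- (m * s2 + m^3) / s2
    g <- ghat; d2 <- d2hat
    for (it in seq_len(maxIter)) {
      gnew <- (nB * t2 * ghat + d2 * gbar) / (nB * t2 + d2)
      ssq <- colSums((Zb - matrix(gnew, nB, ncol(Zb), byrow = TRUE))^2)
      d2new <- (0.5 * ssq + bprior) / (nB / 2 + aprior - 1)
      change <- max(abs(gnew - g), abs(d2new - d2))
      g <- gnew; d2 <- d2new
      if (change < tol) break
    }
    gammaStar[b, ] <- g
    deltaStar[b, ] <- sqrt(d2)
  }
  new("CombatModel", batches = levels(batch), nPerBatch = as.integer(nb),
      alpha = alpha, betaCov = betaCov, sigma = sigma,
      gammaStar = gammaStar, deltaStar = deltaStar,
      covariateNames = colnames(Xc) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a fitted ComBat model
#'
#' Removes the batch location/scale effects estimated by
#' \code{\link{combatFit}} and restores the grand-mean and covariate
#' structure. Works on the fitting data or on held-out subjects from batches
#' seen at fit time.
#'
#' @param model a \linkS4class{CombatModel}.
#' @param features subjects x features matrix with the same feature order as
#'   at fit time.
#' @param batch batch labels; every level must have been seen by the model.
#' @param covariates covariates matching the model's covariate set.
#' @return adjusted features, same shape as the input.
#' @export
combatApply <- function(model, features, batch, covariates = NULL) {
  Y <- as.matrix(features)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model@batches)
  if (length(unseen))
    stop(sprintf("batch label(s) not seen at fit time: %s",
                 paste(unseen, collapse = ", ")))
  nc <- length(model@covariateNames)
  if (nc > 0) {
    if (is.null(covariates)) stop("model was fit with covariates; none supplied")
    Xc <- as.matrix(as.data.frame(covariates))
    storage.mode(Xc) <- "double"
    if (ncol(Xc) != nc) stop("covariate count differs from fit time")
  } else Xc <- matrix(0, nrow(Y), 0)
  n <- nrow(Y); f <- ncol(Y)
  standMean <- matrix(model@alpha, n, f, byrow = TRUE) +
    if (nc) Xc %*% model@betaCov else 0
  sig <- matrix(model@sigma, n, f, byrow = TRUE)
  Z <- (Y - standMean) / sig
  bi <- match(batch, model@batches)
  Zadj <- (Z - model@gammaStar[bi, , drop = FALSE]) /
    model@deltaStar[bi, , drop = FALSE]
  Zadj * sig + standMean
}

setMethod("show", "CombatModel", function(object) {
  cat(sprintf("CombatModel: %d batches (%s), %d features, %d covariates\n",
              length(object@batches),
              paste(sprintf("%s n=%d", object@batches, object@nPerBatch),
                    collapse = ", "),
              length(object@alpha), length(object@covariateNames)))
})
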