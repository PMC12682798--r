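#' Synthetic cohort configuration
#'
#' Parameters of the synthetic connectome cohort generator. Defaults emulate
#' the study conditions the analysis assumes: 92 analysis subjects plus 10
#' independent template subjects, 148 cortical regions (74 per hemisphere),
#' weak interhemispheric connectivity with stronger homotopic (mirror-region)
#' connections, a smooth anterior-posterior connectivity decay within each
#' hemisphere, two scanner batches in a 67/33 split, and IQ-like standard
#' scores with population mean 100 and SD 15 whose individual variation is
#' partly driven by the principal-gradient values of a planted region set.
#'
#' @param nSubjects analysis cohort size; default 92.
#' @param nRegions total region count, half per hemisphere; default 148.
#' @param nTemplateSubjects independent subjects used only to build the
#'   gradient reference template; default 10.
#' @param intraMean peak within-hemisphere expected edge weight; default 1.
#' @param interMean diffuse interhemispheric expected edge weight; default 0.1.
#' @param homotopicMean additional interhemispheric weight concentrated on
#'   mirror-region pairs; default 0.9. Homotopic connections are the
#'   strongest interhemispheric ones anatomically, and because each region's
#'   connectivity profile is sparsified to its strongest edges before the
#'   affinity step, they are what keeps the affinity graph connected across
#'   hemispheres.
#' @param apDecay anterior-posterior connectivity decay length on the [0, 1]
#'   position axis; default 0.5.
#' @param homotopicDecay decay length of the homotopic band; default
#'   \code{apDecay / 10}, i.e. a narrow band around the exact mirror pair, so
#'   the interhemispheric block mean stays well below the intrahemispheric
#'   one.
#' @param hubsPerHemisphere number of hub regions per hemisphere; default 6.
#'   Hubs connect strongly to their whole hemisphere irrespective of
#'   anterior-posterior distance, emulating the hub architecture of real
#'   connectomes; without them a pure 1-D decay degenerates into a chain
#'   whose slow spatial modes would implausibly dominate the hemispheric
#'   organization.
#' @param hubStrength within-hemisphere edge weight of hub regions relative
#'   to \code{intraMean}; default 0.84 (edge weight is the maximum of the
#'   distance-decay term and the hub term).
#' @param noiseSigma SD of the mean-one multiplicative lognormal edge noise;
#'   default 0.4. Keeps counts nonnegative and heteroscedastic like
#'   streamline counts.
#' @param batchProportions batch size proportions summing to 1; default
#'   c(0.67, 0.33).
#' @param iqMean,iqSd population mean and SD of the outcome scores; defaults
#'   100 and 15 (the instrument's standard-score scale).
#' @param relevantRegions character ids (or integer indices) of the planted
#'   signal regions; default 5 spread-out left-hemisphere regions.
#' @param effectSize fraction of outcome variance carried by the planted
#'   gradient signal, in [0, 1); default 0.35.
#' @param batchShift location shift (in feature-SD units) applied to the
#'   minority batch; default 0.5.
#' @param batchScale scale factor applied to the minority batch; default 1.1.
#' @param nScores number of outcome scores sharing the planted regions;
#'   default 1.
#' @param nGradientComponents embedding components computed; default 10.
#' @param sparsity affinity row sparsification; default 0.9.
#' @param seed integer master seed.
#' @return named list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(nSubjects = 92, nRegions = 148,
                             nTemplateSubjects = 10, intraMean = 1,
                             interMean = 0.1, homotopicMean = 0.9,
                             apDecay = 0.5, homotopicDecay = apDecay / 10,
                             hubsPerHemisphere = 6, hubStrength = 0.84,
                             noiseSigma = 0.4,
                             batchProportions = c(0.67, 0.33),
                             iqMean = 100, iqSd = 15,
                             relevantRegions = NULL, effectSize = 0.35,
                             batchShift = 0.5, batchScale = 1.1, nScores = 1,
                             nGradientComponents = 10, sparsity = 0.9,
                             seed = 0) {
  if (nRegions %% 2 != 0) stop("nRegions must be even (half per hemisphere)")
  if (abs(sum(batchProportions) - 1) > 1e-8) stop("batch proportions must sum to 1")
  if (effectSize < 0 || effectSize >= 1) stop("effectSize must lie in [0, 1)")
  nh <- nRegions / 2
  if (is.null(relevantRegions)) {
    idx <- unique(pmax(1, round(nh * c(0.12, 0.3, 0.5, 0.7, 0.88))))
    relevantRegions <- sprintf("L%03d", idx)
  } else if (is.numeric(relevantRegions)) {
    relevantRegions <- .sim_parcellation(nRegions)@regionIds[relevantRegions]
  }
  structure(list(nSubjects = as.integer(nSubjects),
                 nRegions = as.integer(nRegions),
                 nTemplateSubjects = as.integer(nTemplateSubjects),
                 intraMean = intraMean, interMean = interMean,
                 homotopicMean = homotopicMean, apDecay = apDecay,
                 homotopicDecay = homotopicDecay,
                 hubsPerHemisphere = as.integer(hubsPerHemisphere),
                 hubStrength = hubStrength, noiseSigma = noiseSigma,
                 batchProportions = batchProportions,
                 iqMean = iqMean, iqSd = iqSd,
                 relevantRegions = relevantRegions, effectSize = effectSize,
                 batchShift = batchShift, batchScale = batchScale,
                 nScores = as.integer(nScores),
                 nGradientComponents = as.integer(nGradientComponents),
                 sparsity = sparsity, seed = as.integer(seed)),
            class = "simulationConfig")
}

# parcellation of the synthetic cohort: L001..L0nh then R001..R0nh,
# mirror-indexed across hemispheres, anterior-posterior position by index
.sim_parcellation <- function(nRegions) {
  nh <- nRegions / 2
  ids <- c(sprintf("L%03d", seq_len(nh)), sprintf("R%03d", seq_len(nh)))
  Parcellation(ids, rep(c("L", "R"), each = nh), ids)
}

.sim_positions <- function(nRegions) {
  nh <- nRegions / 2
  pos <- (seq_len(nh) - 1) / (nh - 1)
  c(pos, pos)  # mirrored: region i on L and on R share the A-P position
}

# expected (noise-free) edge-weight matrix of the generative model
.sim_expected <- function(config) {
  n <- config$nRegions
  nh <- n / 2
  pos <- .sim_positions(n)
  hemi <- rep(c(0, 1), each = nh)
  dAP <- abs(outer(pos, pos, `-`))
  sameH <- outer(hemi, hemi, `==`)
  nhub <- config$hubsPerHemisphere
  hub <- logical(n)
  if (nhub > 0) {
    hidx <- unique(round(seq(1, nh, length.out = nhub + 2)[-c(1, nhub + 2)]))
    hub[c(hidx, nh + hidx)] <- TRUE
  }
  isHubPair <- outer(hub, hub, `|`)
  intra <- config$intraMean *
    pmax(exp(-dAP / config$apDecay), config$hubStrength * isHubPair)
  E <- ifelse(sameH, intra,
              config$interMean +
                config$homotopicMean * exp(-dAP / config$homotopicDecay))
  diag(E) <- 0
  E
}

#' Simulate one subject's connectome
#'
#' Regions carry a 1-D anterior-posterior coordinate per hemisphere; the
#' expected edge weight decays exponentially with anterior-posterior distance
#' within a hemisphere, and interhemispheric edges combine a weak diffuse
#' baseline with stronger homotopic connections. Mean-one multiplicative
#' lognormal noise perturbs each edge, then the matrix is symmetrized and
#' normalized to unit lower-triangular mass.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param subjectId identifier stored on the result.
#' @return a normalized \linkS4class{Connectome}. Consumes the current RNG
#'   stream; seed externally (or use \code{\link{simulateCohort}}).
#' @export
simulateConnectome <- function(config, subjectId = "sim") {
  E <- .sim_expected(config)
  n <- config$nRegions
  sig <- config$noiseSigma
  noise <- matrix(1, n, n)
  up <- upper.tri(E)
  noise[up] <- exp(stats::rnorm(sum(up), -sig^2 / 2, sig))
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  raw <- E * noise
  p <- .sim_parcellation(n)
  normalizeConnectome(Connectome(symmetrizeConnectome(raw), p,
                                 subjectId = subjectId))
}

#' Simulate outcome scores from gradient features
#'
#' The planted signal is the standardized mean principal-gradient value over
#' the configured relevant regions; scores are
#' \eqn{IQ = \mu + \sigma(\sqrt{e} \cdot signal + \sqrt{1 - e} \cdot
#' \epsilon)} with standard-normal noise, so the population mean and SD hit
#' the instrument scale and \eqn{cor(signal, IQ) = \sqrt{e}}.
#'
#' @param principalGradient numeric subjects x regions matrix of (aligned)
#'   principal-gradient values with region ids as column names.
#' @param config a \code{\link{simulationConfig}}.
#' @param nScores number of scores to draw (shared signal, independent
#'   noise); defaults to \code{config$nScores}.
#' @return numeric subjects x nScores matrix. Consumes the RNG stream.
#' @export
simulateIQ <- function(principalGradient, config, nScores = config$nScores) {
  pg <- as.matrix(principalGradient)
  rr <- config$relevantRegions
  if (!is.null(colnames(pg))) {
    missing <- setdiff(rr, colnames(pg))
    if (length(missing))
      stop(sprintf("relevant region(s) not in the parcellation: %s",
                   paste(missing, collapse = ", ")))
    idx <- match(rr, colnames(pg))
  } else idx <- as.integer(rr)
  signal <- rowMeans(pg[, idx, drop = FALSE])
  signal <- as.numeric(scale(signal))
  e <- config$effectSize
  n <- nrow(pg)
  iq <- vapply(seq_len(nScores), function(s)
    config$iqMean + config$iqSd *
      (sqrt(e) * signal + sqrt(1 - e) * stats::rnorm(n)),
    numeric(n))
  colnames(iq) <- paste0("score", seq_len(nScores))
  iq
}

#' Apply planted scanner batch effects to features
#'
#' Shifts and rescales the minority batch: for each feature,
#' \eqn{x' = m + s_{scale} (x - m) + s_{shift} \cdot sd} where m and sd are
#' the feature's grand mean and SD. With \code{batchShift = 0} and
#' \code{batchScale = 1} features pass through unchanged.
#'
#' @param features numeric subjects x features matrix.
#' @param batch batch labels; the smallest batch receives the effect.
#' @param config a \code{\link{simulationConfig}}.
#' @return shifted features, same shape.
#' @export
addBatchEffects <- function(features, batch, config) {
  x <- as.matrix(features)
  batch <- as.factor(batch)
  minority <- names(which.min(table(batch)))
  idx <- which(batch == minority)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  x[idx, ] <- sweep(sweep(sweep(x[idx, , drop = FALSE], 2, m), 2,
                          rep(config$batchScale, ncol(x)), `*`),
                    2, m + config$batchShift * s, `+`)
  x
}

#' Simulate a full synthetic cohort
#'
#' Generates template and analysis connectomes, computes each subject's
#' diffusion-map gradients, builds the reference template from the
#' independent template subjects by generalized Procrustes analysis, aligns
#' every analysis subject to it, plants the outcome signal in the configured
#' regions, assigns scanner batches (67/33 by default) and covariates, and
#' applies the planted batch effects to the gradient features. Ground truth
#' (relevant regions, effect size, clean features) is stored for recovery
#' tests only and is never consumed by the pipeline.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{SyntheticCohort}. Fully reproducible from
#'   \code{config$seed}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  p <- .sim_parcellation(config$nRegions)
  nT <- config$nTemplateSubjects
  nS <- config$nSubjects

  templ_conn <- lapply(seq_len(nT), function(i)
    simulateConnectome(config, sprintf("template%02d", i)))
  conns <- lapply(seq_len(nS), function(i)
    simulateConnectome(config, sprintf("subject%03d", i)))

  grad <- function(C) connectomeGradients(C, config$nGradientComponents,
                                          config$sparsity)
  templ_sets <- lapply(templ_conn, grad)
  template <- buildTemplate(templ_sets,
                            subjectIds = vapply(templ_conn, subjectId, ""))
  aligned <- lapply(conns, function(C)
    procrustesAlign(grad(C), template)$aligned)

  d <- 2L  # principal + secondary gradient as features
  feats <- vapply(aligned, function(g) g@vectors[, seq_len(d)],
                  matrix(0, config$nRegions, d))
  dimnames(feats) <- list(p@regionIds, paste0("g", seq_len(d)),
                          vapply(conns, subjectId, ""))

  pg <- t(feats[, 1L, ])
  colnames(pg) <- p@regionIds
  iq <- simulateIQ(pg, config)

  sizes <- round(config$batchProportions * nS)
  sizes[length(sizes)] <- nS - sum(sizes[-length(sizes)])
  batch <- factor(rep(paste0("scanner", LETTERS[seq_along(sizes)]), sizes))
  batch <- batch[sample.int(nS)]

  covariates <- data.frame(
    gestationalAge = stats::rnorm(nS, 38.9, 1.5),
    sexMale = stats::rbinom(nS, 1, 0.54),
    nLargeTranslation = stats::rnbinom(nS, size = 0.4, mu = 0.32),
    nExcludedDWI = stats::rnbinom(nS, size = 1.1, mu = 1.46),
    ageAtScanMonths = stats::rnorm(nS, 12.95, 0.94))

  flat <- t(vapply(seq_len(nS), function(i) as.numeric(feats[, , i]),
                   numeric(config$nRegions * d)))
  shifted <- addBatchEffects(flat, batch, config)
  featsShifted <- feats
  for (i in seq_len(nS))
    featsShifted[, , i] <- matrix(shifted[i, ], config$nRegions, d)

  new("SyntheticCohort", connectomes = conns, features = featsShifted,
      iq = iq, batch = batch, covariates = covariates, template = template,
      parcellation = p,
      groundTruth = list(relevantRegions = config$relevantRegions,
                         effectSize = config$effectSize,
                         signal = as.numeric(scale(rowMeans(
                           pg[, match(config$relevantRegions, colnames(pg))]))),
                         cleanFeatures = feats),
      config = unclass(config))
}

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects, %d regions, %d outcome score(s)\n",
              length(object@connectomes), nrow(object@features),
              ncol(object@iq)))
  cat("  batches:", paste(sprintf("%s n=%d", levels(object@batch),
                                  table(object@batch)), collapse = ", "), "\n")
  cat(sprintf("  planted effect size %.2f in regions %s\n",
              object@groundTruth$effectSize,
              paste(object@groundTruth$relevantRegions, collapse = ", ")))
})

#' Export a synthetic cohort to plain-text files
#'
#' Writes the same formats the analysis pipeline consumes: one delimited
#' connectome matrix per subject, the parcellation TSV, a covariate table
#' (with batch and outcome scores) and a \code{ground_truth.json} sidecar
#' that the pipeline never reads.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
exportCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeParcellation(cohort@parcellation, file.path(dir, "parcellation.tsv"))
  for (C in cohort@connectomes)
    writeConnectome(C, file.path(dir, paste0(subjectId(C), ".csv")))
  tab <- cbind(data.frame(subject = vapply(cohort@connectomes, subjectId, ""),
                          batch = cohort@batch),
               cohort@covariates, cohort@iq)
  utils::write.csv(tab, file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(cohort@groundTruth[c("relevantRegions", "effectSize",
                                            "signal")],
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
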