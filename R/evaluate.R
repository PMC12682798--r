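#' Build a repeated k-fold cross-validation plan
#'
#' Balanced shuffled folds (sizes differing by at most 1) for each
#' repetition, deterministic given \code{masterSeed}.
#'
#' @param n number of subjects.
#' @param k folds per repetition; default 10.
#' @param nRepetitions repetitions with independent shuffles; default 10.
#' @param masterSeed integer seed.
#' @return list of class \code{cvPlan} with per-repetition fold assignment
#'   vectors (integers in 1..k).
#' @export
makeCVPlan <- function(n, k = 10, nRepetitions = 10, masterSeed = 0) {
  if (k > n) stop("k must not exceed the number of subjects")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(masterSeed)
  folds <- lapply(seq_len(nRepetitions), function(r) {
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    assign <- rep(seq_len(k), times = sizes)
    assign[sample.int(n)]
  })
  structure(list(n = n, k = k, nRepetitions = nRepetitions,
                 masterSeed = masterSeed, folds = folds),
            class = "cvPlan")
}

#' Prediction metrics
#'
#' Mean absolute error on the IQ scale plus Spearman's rank and Pearson's
#' product-moment correlations between predictions and observations.
#'
#' @param pred,obs numeric vectors on the IQ scale, length >= 3.
#' @return named list with \code{mae}, \code{spearman}, \code{pearson},
#'   \code{r2}.
#' @export
predictionMetrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (length(pred) < 3) stop("at least three subjects required")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("correlation undefined for constant vectors")
  r <- stats::cor(pred, obs)
  list(mae = mean(abs(pred - obs)),
       spearman = stats::cor(pred, obs, method = "spearman"),
       pearson = r, r2 = r^2)
}

#' Permutation test of the prediction-observation association
#'
#' One-sided test of positive association: the observed correlation is
#' compared with the null distribution obtained by shuffling the predicted
#' values, with the add-one correction
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}. When the
#' number of distinct permutations is at most \code{nPerm} the test
#' enumerates all of them exhaustively and \eqn{p = \#\{r_{perm} \ge
#' r_{obs}\} / n!} is exact.
#'
#' @param pred,obs numeric vectors, length >= 3 (>= 5 recommended).
#' @param nPerm number of random shuffles; default 10000.
#' @param seed integer seed for the shuffles.
#' @param method correlation type, \code{"spearman"} (default) or
#'   \code{"pearson"}.
#' @return list with \code{p.value}, \code{statistic}, \code{nPerm},
#'   \code{exhaustive}.
#' @export
permutationPvalue <- function(pred, obs, nPerm = 10000, seed = 0,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- length(pred)
  if (length(obs) != n) stop("pred and obs must have equal length")
  stat <- stats::cor(pred, obs, method = method)
  nfact <- factorial(n)
  if (n <= 10 && nfact <= nPerm) {
    perms <- .permutations(n)
    null <- apply(perms, 1, function(ix) stats::cor(pred[ix], obs, method = method))
    p <- sum(null >= stat - 1e-12) / nfact
    return(list(p.value = p, statistic = stat, nPerm = nfact, exhaustive = TRUE))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i)
    stats::cor(pred[sample.int(n)], obs, method = method), numeric(1))
  list(p.value = (1 + sum(null >= stat)) / (1 + nPerm),
       statistic = stat, nPerm = nPerm, exhaustive = FALSE)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Naive mean-predictor baseline
#'
#' Assigns the training-set mean to every test subject. Pooled across folds
#' the fold means differ, so pooled correlations of the baseline are defined
#' (and typically negative).
#'
#' @param trainTargets numeric training targets.
#' @param testSize number of test predictions to emit.
#' @return constant numeric vector of length \code{testSize}.
#' @export
naiveBaseline <- function(trainTargets, testSize) {
  if (!length(trainTargets)) stop("empty training targets")
  rep(mean(trainTargets), testSize)
}

## normalization used inside the CV harness ----------------------------------

# per-subject feature normalization producing the list of N x d matrices the
# GCN consumes; `flat` is subjects x (N*d). In across-subject scope the
# scaling statistics are computed on `statRows` (the training folds when
# leakage must be avoided) and applied to everyone.
.normalized_feature_list <- function(flat, nRegions, d, hemisphere, scope,
                                     statRows = seq_len(nrow(flat))) {
  n <- nrow(flat)
  if (scope == "across_subjects") {
    mu <- colMeans(flat[statRows, , drop = FALSE])
    sdv <- apply(flat[statRows, , drop = FALSE], 2, stats::sd)
    if (any(sdv == 0)) stop("zero across-subject variance; cannot standardize")
    flat <- sweep(sweep(flat, 2, mu), 2, sdv, `/`)
    lapply(seq_len(n), function(i) matrix(flat[i, ], nRegions, d))
  } else {
    lapply(seq_len(n), function(i)
      zscoreByHemisphere(matrix(flat[i, ], nRegions, d), hemisphere))
  }
}

#' Run the repeated cross-validated prediction pipeline
#'
#' For each repetition and fold: harmonize the gradient features with ComBat
#' (\code{combatMode = "combined"} reproduces the reference protocol of
#' fitting on train + test jointly within the fold; \code{"train_only"} fits
#' on the training folds only and applies the stored model to the test
#' fold), normalize features (hemisphere-wise z-score per subject) and
#' targets (min-max to [0, 1]), train the GCN on the training folds, and
#' predict the held-out fold. Out-of-fold predictions are pooled per
#' repetition and the metrics computed once per repetition, then summarized
#' as mean and SD across repetitions.
#'
#' Gradient alignment to the external reference template is a deterministic
#' per-subject operation and is therefore performed upstream (the
#' \code{cohort} features are already aligned); its per-fold result would be
#' identical by construction.
#'
#' @param cohort a \linkS4class{SyntheticCohort}, or a list with elements
#'   \code{features} (N x d x n array, aligned), \code{connectomes} (list of
#'   adjacency matrices or \linkS4class{Connectome}s), \code{iq} (numeric
#'   vector), \code{batch}, \code{covariates}, \code{hemisphere}.
#' @param config a \code{\link{gcnConfig}}.
#' @param plan a \code{\link{makeCVPlan}} plan for the cohort size.
#' @param combatMode \code{"combined"} (default) or \code{"train_only"}; or
#'   \code{"none"} to skip harmonization.
#' @param outcome column of the cohort's IQ matrix to predict; default 1.
#' @param keepModels keep the trained per-fold models (needed for
#'   attribution); default FALSE.
#' @return list with \code{predictions} (data.frame: subject, repetition,
#'   fold, predicted, observed on the IQ scale), \code{perRepetition}
#'   (data.frame of pooled metrics), \code{summary} (mean and SD across
#'   repetitions) and optionally \code{models}.
#' @export
runCrossValidation <- function(cohort, config = gcnConfig(), plan,
                               combatMode = c("combined", "train_only", "none"),
                               outcome = 1, keepModels = FALSE) {
  combatMode <- match.arg(combatMode)
  ch <- .as_cohort_list(cohort, outcome)
  n <- length(ch$iq)
  if (plan$n != n) stop("plan size does not match the cohort")
  d <- config$nInputComponents
  nRegions <- dim(ch$features)[1]
  if (dim(ch$features)[2] < d)
    stop("cohort features carry fewer components than the config requests")
  flat <- t(vapply(seq_len(n), function(i) as.numeric(ch$features[, seq_len(d), i]),
                   numeric(nRegions * d)))
  y01 <- minmaxIQ(ch$iq)

  # combined-mode ComBat is fit on all subjects within every fold, which is
  # the same model each time; compute it once
  if (combatMode == "combined") {
    model <- combatFit(flat, ch$batch, ch$covariates)
    flat_comb <- combatApply(model, flat, ch$batch, ch$covariates)
  }

  # the eigendecomposition behind the spectral filters depends only on each
  # subject's adjacency, so it is computed once and reused across folds
  gb <- .graph_bundles(ch$connectomes, config$K)
  preds <- list(); metrics <- list(); models <- list()
  for (r in seq_len(plan$nRepetitions)) {
    fold_of <- plan$folds[[r]]
    rep_pred <- numeric(n)
    for (f in sort(unique(fold_of))) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      adj_flat <- switch(combatMode,
        combined = flat_comb,
        train_only = {
          m <- combatFit(flat[train, , drop = FALSE], ch$batch[train],
                         if (is.null(ch$covariates)) NULL
                         else ch$covariates[train, , drop = FALSE])
          out <- flat
          out[train, ] <- combatApply(m, flat[train, , drop = FALSE],
                                      ch$batch[train],
                                      if (is.null(ch$covariates)) NULL
                                      else ch$covariates[train, , drop = FALSE])
          out[test, ] <- combatApply(m, flat[test, , drop = FALSE],
                                     ch$batch[test],
                                     if (is.null(ch$covariates)) NULL
                                     else ch$covariates[test, , drop = FALSE])
          out
        },
        none = flat)
      X <- .normalized_feature_list(adj_flat, nRegions, d, ch$hemisphere,
                                    config$zscoreScope,
                                    statRows = if (combatMode == "train_only")
                                      train else seq_len(n))
      foldcfg <- config
      foldcfg$seed <- config$seed + 1000L * r + f
      fit <- trainGCN(ch$connectomes[train], X[train], y01[train], foldcfg,
                      hemisphere = ch$hemisphere, graphBundles = gb[train])
      rep_pred[test] <- gcnForward(fit, ch$connectomes[test], X[test],
                                   graphBundles = gb[test])
      if (keepModels)
        models[[length(models) + 1L]] <-
          list(model = fit, repetition = r, fold = f, test = test,
               features = X, y01 = y01)
    }
    predIQ <- inverseMinmaxIQ(rep_pred)
    m <- predictionMetrics(predIQ, ch$iq)
    metrics[[r]] <- data.frame(repetition = r, mae = m$mae,
                               spearman = m$spearman, pearson = m$pearson,
                               r2 = m$r2)
    preds[[r]] <- data.frame(subject = seq_len(n), repetition = r,
                             fold = fold_of, predicted = predIQ,
                             observed = ch$iq)
  }
  perRep <- do.call(rbind, metrics)
  summ <- data.frame(
    metric = c("mae", "spearman", "pearson", "r2"),
    mean = vapply(c("mae", "spearman", "pearson", "r2"),
                  function(k) mean(perRep[[k]]), numeric(1)),
    sd = vapply(c("mae", "spearman", "pearson", "r2"),
                function(k) stats::sd(perRep[[k]]), numeric(1)))
  out <- list(predictions = do.call(rbind, preds), perRepetition = perRep,
              summary = summ)
  if (keepModels) out$models <- models
  out
}

# normalize the cohort argument to a plain list; harmonization protects the
# four protocol covariates (gestational age, sex, and the two motion counts)
.combat_covariate_names <- c("gestationalAge", "sexMale", "nLargeTranslation",
                             "nExcludedDWI")

.as_cohort_list <- function(cohort, outcome = 1) {
  if (is(cohort, "SyntheticCohort")) {
    keep <- intersect(.combat_covariate_names, names(cohort@covariates))
    list(features = cohort@features,
         connectomes = cohort@connectomes,
         iq = cohort@iq[, outcome],
         batch = cohort@batch,
         covariates = cohort@covariates[, keep, drop = FALSE],
         hemisphere = cohort@parcellation@hemisphere)
  } else {
    iq <- cohort$iq
    if (is.matrix(iq)) iq <- iq[, outcome]
    list(features = cohort$features, connectomes = cohort$connectomes,
         iq = iq, batch = cohort$batch, covariates = cohort$covariates,
         hemisphere = cohort$hemisphere)
  }
}
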