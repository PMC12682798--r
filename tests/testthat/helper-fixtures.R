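# Shared fixtures: tiny parcellations, toy connectomes, and a cached small
# synthetic cohort so expensive generation runs once per test session.

toy_parcellation <- function(n, nh = n %/% 2) {
  Parcellation(sprintf("r%02d", seq_len(n)),
               rep(c("L", "R"), c(nh, n - nh)))
}

# random symmetric nonnegative connectome matrix with zero diagonal
random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

.fixture_env <- new.env(parent = emptyenv())

# small planted-signal cohort reused across test files
small_cohort <- function(seed = 3) {
  key <- paste0("coh", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- simulationConfig(seed = seed, nSubjects = 40, nRegions = 60,
                            nTemplateSubjects = 5)
    .fixture_env[[key]] <- suppressWarnings(simulateCohort(cfg))
  }
  .fixture_env[[key]]
}

# a small trained model plus the data it was trained on (cached)
small_trained_model <- function(seed = 3) {
  key <- paste0("fit", seed)
  if (is.null(.fixture_env[[key]])) {
    coh <- small_cohort(seed)
    ch <- GradIQ:::.as_cohort_list(coh, 1)
    n <- length(ch$iq)
    N <- dim(ch$features)[1]
    flat <- t(vapply(seq_len(n), function(i) as.numeric(ch$features[, 1:2, i]),
                     numeric(N * 2)))
    X <- GradIQ:::.normalized_feature_list(flat, N, 2, ch$hemisphere,
                                           "across_subjects")
    y <- minmaxIQ(ch$iq)
    cfg <- gcnConfig(seed = seed)
    fit <- trainGCN(ch$connectomes, X, y, cfg, hemisphere = ch$hemisphere)
    .fixture_env[[key]] <- list(fit = fit, X = X, y = y, ch = ch)
  }
  .fixture_env[[key]]
}

# independent R-side forward pass (explicit Chebyshev recursion + dense MLP),
# used as the oracle for the compiled spectral implementation
reference_forward <- function(params, A, X, config) {
  op <- buildGraphOperator(A)
  H <- as.matrix(X)
  for (l in seq_along(params$Wg)) {
    cheb <- chebyshevFeatures(op, H, config$K)
    Zl <- do.call(cbind, cheb)
    H <- pmax(Zl %*% params$Wg[[l]], 0)
  }
  v <- as.numeric(H)
  for (m in seq_along(params$Wm)) {
    v <- as.numeric(t(params$Wm[[m]]) %*% v + params$bm[[m]])
    if (m < length(params$Wm)) v <- pmax(v, 0)
  }
  v
}
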