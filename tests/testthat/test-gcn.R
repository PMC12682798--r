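test_that("graph operator matches hand-computed Laplacians and spectra bounds", {
  op <- buildGraphOperator(matrix(c(0, 1, 1, 0), 2))
  expect_equal(op@laplacian, matrix(c(1, -1, -1, 1), 2))
  expect_equal(sort(eigen(op@laplacian, symmetric = TRUE)$values), c(0, 2))
  expect_equal(op@lambdaMax, 2)
  expect_equal(op@scaledLaplacian, matrix(c(0, -1, -1, 0), 2))

  # complete graph: null space is the constant vector
  A <- matrix(1, 5, 5); diag(A) <- 0
  op5 <- buildGraphOperator(A)
  es <- eigen(op5@laplacian, symmetric = TRUE)
  expect_equal(min(es$values), 0, tolerance = 1e-12)
  v0 <- es$vectors[, which.min(es$values)]
  expect_equal(abs(v0), rep(abs(v0[1]), 5), tolerance = 1e-10)

  # random connected weighted graph: dense-oracle spectra bounds
  A8 <- random_symmetric(8, seed = 61) + 0.05
  diag(A8) <- 0
  op8 <- buildGraphOperator(A8)
  lam <- eigen(op8@laplacian, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(lam >= -1e-10 & lam <= 2 + 1e-10))
  lamT <- eigen(op8@scaledLaplacian, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(lamT >= -1 - 1e-10 & lamT <= 1 + 1e-10))

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  rownames(iso) <- colnames(iso) <- c("a", "b", "c")
  expect_error(buildGraphOperator(Connectome(iso,
    Parcellation(c("a", "b", "c"), c("L", "L", "R")))), "zero-degree.*c")
})

test_that("Chebyshev recursion equals explicit matrix polynomials", {
  A <- random_symmetric(6, seed = 62) + 0.05
  diag(A) <- 0
  op <- buildGraphOperator(A)
  set.seed(63)
  H <- matrix(rnorm(6 * 2), 6)

  expect_equal(chebyshevFeatures(op, H, 0), list(H))

  Lt <- op@scaledLaplacian
  cheb <- chebyshevFeatures(op, H, 5)
  # explicit polynomial oracle: T0=I, T1=Lt, T2=2Lt^2-I, T3=4Lt^3-3Lt, ...
  T0 <- diag(6); T1 <- Lt
  mats <- list(T0, T1)
  for (k in 3:6) mats[[k]] <- 2 * Lt %*% mats[[k - 1]] - mats[[k - 2]]
  for (k in 1:6)
    expect_equal(cheb[[k]], mats[[k]] %*% H, tolerance = 1e-8)
  expect_equal(cheb[[3]], (2 * Lt %*% Lt - diag(6)) %*% H, tolerance = 1e-10)

  # Ltilde = I (hypothetical): T_k(1) = 1 for all k
  opI <- new("GraphOperator", adjacency = diag(4), degree = rep(1, 4),
             laplacian = diag(4), scaledLaplacian = diag(4), lambdaMax = 1)
  chebI <- chebyshevFeatures(opI, H[1:4, ], 3)
  for (k in 1:4) expect_equal(chebI[[k]], H[1:4, ])
})

test_that("compiled forward pass agrees with the explicit R reference", {
  set.seed(64)
  N <- 10
  A <- random_symmetric(N, seed = 64) + 0.05; diag(A) <- 0
  X <- matrix(rnorm(N * 2), N)
  cfg <- gcnConfig(seed = 7)
  set.seed(cfg$seed)
  params <- initGCNParams(cfg, N)
  got <- gcnForward(params, list(A), list(X), cfg)
  want <- reference_forward(params, A, X, cfg)
  expect_equal(got, want, tolerance = 1e-8)

  # all-zero weights: prediction equals the final bias
  zero <- params
  zero$Wg <- lapply(zero$Wg, function(w) w * 0)
  zero$Wm <- lapply(zero$Wm, function(w) w * 0)
  zero$bm <- lapply(zero$bm, function(b) b * 0)
  zero$bm[[length(zero$bm)]] <- 0.37
  expect_equal(gcnForward(zero, list(A), list(X), cfg), 0.37)

  # consistent relabeling of regions (inputs, adjacency, and the readout
  # rows that index regions) leaves the prediction unchanged
  perm <- sample(N)
  pparams <- params
  w <- cfg$layerWidths[length(cfg$layerWidths)]
  rowperm <- as.vector(outer(perm, (seq_len(w) - 1) * N, `+`))
  pparams$Wm[[1]] <- pparams$Wm[[1]][rowperm, , drop = FALSE]
  expect_equal(gcnForward(pparams, list(A[perm, perm]), list(X[perm, ]), cfg),
               got, tolerance = 1e-8)
})

test_that("a K=0 width-1 reduction behaves as a per-node linear map", {
  N <- 6
  A <- random_symmetric(N, seed = 65) + 0.1; diag(A) <- 0
  set.seed(66)
  X <- matrix(abs(rnorm(N)), N, 1)           # positive: rectifier passes through
  cfg <- gcnConfig(K = 0, layerWidths = 1, mlpWidths = integer(0),
                   nInputComponents = 1, seed = 1)
  w0 <- 1.5
  wm <- matrix(1 / N, N, 1)                  # averaging readout
  params <- list(Wg = list(matrix(w0, 1, 1)), Wm = list(wm), bm = list(0.25))
  got <- gcnForward(params, list(A), list(X), cfg)
  expect_equal(got, mean(w0 * X) + 0.25, tolerance = 1e-12)
})

test_that("analytic parameter gradients match finite differences", {
  set.seed(67)
  N <- 8
  A <- random_symmetric(N, seed = 67) + 0.05; diag(A) <- 0
  X <- matrix(rnorm(N * 2), N)
  cfg <- gcnConfig(layerWidths = c(3, 3), mlpWidths = 4, seed = 2)
  set.seed(cfg$seed)
  params <- initGCNParams(cfg, N)
  bundle <- GradIQ:::precomputeSubject(A, X, cfg$K)
  g <- GradIQ:::gcn_param_grad_cpp(list(bundle), 1.0, params$Wg, params$Wm,
                                   params$bm, cfg$K)
  fd <- function(getter, setter, eps = 1e-6) {
    p1 <- setter(params, +eps)
    p2 <- setter(params, -eps)
    (gcnForward(p1, list(A), list(X), cfg) -
       gcnForward(p2, list(A), list(X), cfg)) / (2 * eps)
  }
  for (probe in list(c(1, 2, 1), c(2, 5, 3))) {
    l <- probe[1]; i <- probe[2]; j <- probe[3]
    num <- fd(NULL, function(p, e) { p$Wg[[l]][i, j] <- p$Wg[[l]][i, j] + e; p })
    expect_equal(g$Wg[[l]][i, j], num, tolerance = 1e-5)
  }
  num <- fd(NULL, function(p, e) { p$Wm[[1]][3, 2] <- p$Wm[[1]][3, 2] + e; p })
  expect_equal(g$Wm[[1]][3, 2], num, tolerance = 1e-5)
  num <- fd(NULL, function(p, e) { p$bm[[2]][1] <- p$bm[[2]][1] + e; p })
  expect_equal(g$bm[[2]][1], num, tolerance = 1e-5)
})

test_that("Siamese loss equals the ordered-pair double loop and is shift invariant", {
  expect_equal(siameseLoss(c(1, 2), c(1, 3)), 2)   # (-1+2)^2 + (1-2)^2

  set.seed(68)
  y <- rnorm(5); f <- rnorm(5)
  oracle <- 0
  for (i in 1:5) for (j in 1:5) if (i != j)
    oracle <- oracle + ((y[i] - y[j]) - (f[i] - f[j]))^2
  expect_equal(siameseLoss(y, f), oracle)

  for (cst in c(-3, 0.1, 7))
    expect_equal(siameseLoss(y, f + cst), siameseLoss(y, f))
  expect_equal(siameseLoss(y, y + 0.42), 0)
  expect_gte(siameseLoss(y, f), 0)
  expect_warning(s1 <- siameseLoss(1, 2), "fewer than two")
  expect_equal(s1, 0)
})

test_that("total loss composes squared error and the weighted Siamese term", {
  y <- c(1, 2); f <- c(1, 3)
  expect_equal(totalLoss(y, f, 10), 1 + 10 * 2)
  expect_equal(totalLoss(y, y, 10), 0)
  set.seed(69)
  y5 <- rnorm(5); f5 <- rnorm(5)
  expect_equal(totalLoss(y5, f5, 0), sum((y5 - f5)^2))
  expect_error(totalLoss(y5, f5, -1), "nonnegative")
})

test_that("hemisphere z-scoring standardizes and is affine invariant", {
  hemi <- rep(c("L", "R"), c(4, 4))
  set.seed(70)
  x <- matrix(rnorm(8 * 2), 8)
  z <- zscoreByHemisphere(x, hemi)
  for (h in c("L", "R")) for (j in 1:2) {
    expect_equal(mean(z[hemi == h, j]), 0, tolerance = 1e-10)
    expect_equal(sd(z[hemi == h, j]), 1, tolerance = 1e-10)
  }
  # affine transforms per hemisphere change nothing
  x2 <- x
  x2[hemi == "L", ] <- 3 * x2[hemi == "L", ] + 5
  x2[hemi == "R", ] <- -2 * x2[hemi == "R", ] + 1
  z2 <- zscoreByHemisphere(x2, hemi)
  expect_equal(abs(z2), abs(z), tolerance = 1e-10)
  expect_equal(z2[hemi == "L", ], z[hemi == "L", ], tolerance = 1e-10)

  # hand-computed 4-region toy
  xt <- matrix(c(1, 3, 2, 6), 4, 1)
  zt <- zscoreByHemisphere(xt, c("L", "L", "R", "R"))
  expect_equal(as.numeric(zt),
               c((1 - 2) / sqrt(2), (3 - 2) / sqrt(2),
                 (2 - 4) / sqrt(8), (6 - 4) / sqrt(8)))
  expect_error(zscoreByHemisphere(matrix(1, 4, 1), c("L", "L", "R", "R")),
               "zero within-hemisphere variance")
})

test_that("IQ min-max normalization uses the fixed 50-150 anchors", {
  expect_equal(minmaxIQ(100), 0.5)
  expect_equal(minmaxIQ(c(50, 150)), c(0, 1))
  set.seed(71)
  x <- runif(20, 55, 145)
  expect_equal(inverseMinmaxIQ(minmaxIQ(x)), x, tolerance = 1e-12)
  expect_warning(minmaxIQ(160), "outside")
})

test_that("training is seed-deterministic and reduces the training loss", {
  tm <- small_trained_model()
  fit <- tm$fit
  expect_lt(tail(fit@epochLoss, 1), fit@epochLoss[1])
  # planted-signal cohort: final training-set rank correlation is high
  pred <- gcnForward(fit, tm$ch$connectomes, tm$X)
  expect_gte(cor(pred, tm$y, method = "spearman"), 0.8)

  # bit-identical rerun under the same seed
  cfg <- fit@config
  cfg <- do.call(gcnConfig, cfg[setdiff(names(cfg), character(0))])
  refit <- trainGCN(tm$ch$connectomes, tm$X, tm$y, cfg,
                    hemisphere = tm$ch$hemisphere)
  expect_identical(refit@epochLoss, fit@epochLoss)
  expect_identical(refit@params, fit@params)
})
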