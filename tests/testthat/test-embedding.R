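test_that("cosine affinity matches direct computation and handles degeneracy", {
  # identical rows -> affinity 1
  m <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, byrow = TRUE)
  m[1, ] <- m[2, ] <- c(1, 1, 2)
  W <- cosineAffinity(m, sparsity = 0)
  expect_equal(W[1, 2], 1)

  # disjoint support -> 0
  d <- rbind(c(1, 0), c(0, 1))
  expect_equal(cosineAffinity(d, sparsity = 0)[1, 2], 0)

  # direct dot-product oracle
  t2 <- rbind(c(1, 0), c(1, 1))
  expect_equal(cosineAffinity(t2, sparsity = 0)[1, 2], 1 / sqrt(2))

  # range, symmetry, unit diagonal on random nonnegative input
  r <- random_symmetric(20, seed = 3)
  W <- cosineAffinity(r, sparsity = 0.5)
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(1, 20))

  # zero row after sparsification is named in the error
  z <- random_symmetric(4, seed = 4)
  z[2, ] <- 0; z[, 2] <- 0
  rownames(z) <- colnames(z) <- letters[1:4]
  expect_error(cosineAffinity(z, sparsity = 0), "degenerate region.*b")
})

test_that("diffusion map matches a dense spectral oracle on a toy graph", {
  set.seed(21)
  m <- random_symmetric(5, seed = 21) + 0.2
  diag(m) <- 0
  W <- cosineAffinity(m, sparsity = 0)
  alpha <- 0.5
  gs <- diffusionMap(W, nComponents = 3, alpha = alpha)

  # independent dense oracle: explicit alpha-normalization, row-stochastic P,
  # full (non-symmetric) eigendecomposition
  d <- rowSums(W)
  K <- W / outer(d^alpha, d^alpha)
  P <- K / rowSums(K)
  eg <- eigen(P)
  ord <- order(-Re(eg$values))
  lam <- Re(eg$values[ord])
  vec <- Re(eg$vectors[, ord])
  expect_equal(lam[1], 1, tolerance = 1e-10)          # trivial eigenvalue
  expect_equal(gradientEigenvalues(gs), lam[2:4], tolerance = 1e-8)
  for (j in 1:3) {
    a <- gradientVectors(gs)[, j]
    b <- vec[, j + 1]
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-8)
    # same vector up to sign after matching the lambda/(1-lambda) scaling
    b <- b / sqrt(sum(b^2)) * sqrt(sum(a^2))
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("two weakly coupled blocks separate by sign of the principal gradient", {
  n <- 8
  W <- matrix(1e-3, n, n)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  gs <- diffusionMap(W, nComponents = 1)   # rank-one blocks leave one mode
  pg <- gradientVectors(gs)[, 1]
  expect_true(all(sign(pg[1:4]) == sign(pg[1])))
  expect_true(all(sign(pg[5:8]) == -sign(pg[1])))
})

test_that("diffusion map is equivariant under node relabeling and affinity scaling", {
  W <- cosineAffinity(random_symmetric(7, seed = 8) + 0.1, sparsity = 0)
  gs <- diffusionMap(W, nComponents = 3)
  set.seed(9)
  perm <- sample(7)
  gsp <- diffusionMap(W[perm, perm], nComponents = 3)
  for (j in 1:3) {
    a <- gradientVectors(gs)[perm, j]
    b <- gradientVectors(gsp)[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  # uniform scaling of W leaves the embedding unchanged (alpha = 0.5)
  gss <- diffusionMap(3.7 * W, nComponents = 3)
  expect_equal(gradientVectors(gss), gradientVectors(gs), tolerance = 1e-10)
  expect_equal(gradientEigenvalues(gss), gradientEigenvalues(gs),
               tolerance = 1e-10)
})

test_that("diffusion map rejects disconnected graphs and excessive rank", {
  W <- diag(2) %x% matrix(1, 3, 3)      # two disconnected cliques
  expect_error(diffusionMap(W, 2), "disconnected")
  Wc <- cosineAffinity(random_symmetric(5, seed = 2) + 0.1, sparsity = 0)
  expect_error(diffusionMap(Wc, 5), "nComponents")
})

test_that("explanation ratios are eigenvalue shares of the retained set", {
  expect_equal(explanationRatio(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(explanationRatio(3.2), 1)
  set.seed(13)
  ev <- sort(runif(6), decreasing = TRUE)
  oracle <- vapply(ev, function(x) x / sum(ev), numeric(1))  # division loop
  expect_equal(explanationRatio(ev), oracle)
  expect_equal(sum(explanationRatio(ev)), 1)
  # invariant to rescaling
  expect_equal(explanationRatio(10 * ev), explanationRatio(ev))
  expect_error(explanationRatio(numeric(0)), "empty")
  # the GradientSet accessor agrees with its eigenvalues
  gs <- diffusionMap(cosineAffinity(random_symmetric(6, seed = 1) + 0.1, 0), 3)
  expect_equal(explanationRatio(gs),
               explanationRatio(gradientEigenvalues(gs)))
})

test_that("hemisphere-specific gradients align right to left", {
  # mirror-symmetric connectome: left and right blocks identical
  nh <- 10
  block <- random_symmetric(nh, seed = 17) + 0.1
  diag(block) <- 0
  m <- matrix(0.01, 2 * nh, 2 * nh)
  m[1:nh, 1:nh] <- block
  m[nh + 1:nh, nh + 1:nh] <- block
  diag(m) <- 0
  C <- Connectome(m, toy_parcellation(2 * nh, nh))
  hg <- hemisphericGradients(C, nComponents = 3, sparsity = 0)
  expect_true(hg$alignedRightToLeft)
  expect_true(isAligned(hg$right))
  for (j in 1:3)
    expect_gte(abs(cor(gradientVectors(hg$left)[, j],
                       gradientVectors(hg$right)[, j])), 0.99)

  # zeroing the interhemispheric block beforehand changes nothing (masking)
  mz <- m; mz[1:nh, nh + 1:nh] <- 0; mz[nh + 1:nh, 1:nh] <- 0
  hg2 <- hemisphericGradients(Connectome(mz, toy_parcellation(2 * nh, nh)),
                              nComponents = 3, sparsity = 0)
  expect_equal(gradientVectors(hg2$left), gradientVectors(hg$left))

  # per-hemisphere eigenvalues match the dense oracle on each submatrix
  halves <- splitHemispheres(C)
  for (h in halves) {
    W <- cosineAffinity(h, sparsity = 0)
    d <- rowSums(W); K <- W / outer(sqrt(d), sqrt(d)); P <- K / rowSums(K)
    lam <- sort(Re(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
    gs <- connectomeGradients(h, nComponents = 3, sparsity = 0)
    expect_equal(gradientEigenvalues(gs), lam[2:4], tolerance = 1e-8)
  }
})

test_that("gradients round-trip through TSV with a JSON sidecar", {
  gs <- connectomeGradients(Connectome(random_symmetric(12, seed = 30) + 0.05,
                                       toy_parcellation(12, 6)),
                            nComponents = 3, sparsity = 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGradients(gs, f)
  tab <- read.delim(f)
  expect_equal(as.matrix(tab[, -1]), unname(gradientVectors(gs)),
               ignore_attr = TRUE)
  side <- jsonlite::read_json(sub("tsv$", "json", f), simplifyVector = TRUE)
  expect_equal(side$eigenvalues, gradientEigenvalues(gs), tolerance = 1e-12)
})
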