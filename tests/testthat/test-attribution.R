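# a hand-built model that is exactly linear on positive inputs:
# f(x) = sum_i c_i x_i + b through an identity GCN layer and linear readout
linear_model <- function(cvec, N, b = 0) {
  cfg <- gcnConfig(K = 0, layerWidths = 1, mlpWidths = integer(0),
                   nInputComponents = 1, seed = 1)
  params <- list(Wg = list(matrix(1, 1, 1)),
                 Wm = list(matrix(cvec, N, 1)), bm = list(b))
  new("GCNModel", params = params, config = unclass(cfg),
      epochLoss = numeric(0), hemisphere = character(0))
}

test_that("saliency of a linear reduction equals the absolute coefficients", {
  N <- 6
  A <- random_symmetric(N, seed = 91) + 0.1; diag(A) <- 0
  cvec <- c(3, -2, 0, 1, 0, 0.5)
  model <- linear_model(cvec, N)
  X <- matrix(abs(rnorm(N, 2)), N, 1)
  sal <- saliencyMap(model, list(A), list(X))
  expect_equal(as.numeric(sal[[1]]), abs(cvec), tolerance = 1e-10)
  signed <- saliencyMap(model, list(A), list(X), signed = TRUE)
  expect_equal(as.numeric(signed[[1]]), cvec, tolerance = 1e-10)

  # constant model: all saliency zero
  zero <- linear_model(rep(0, N), N, b = 2)
  expect_equal(as.numeric(saliencyMap(zero, list(A), list(X))[[1]]),
               rep(0, N))
})

test_that("input gradients match central finite differences", {
  tm <- small_trained_model()
  A <- tm$ch$connectomes[[1]]
  X <- tm$X[[1]]
  model <- tm$fit
  sal <- saliencyMap(model, list(A), list(X), signed = TRUE)[[1]]
  eps <- 1e-5
  for (probe in list(c(3, 1), c(20, 2), c(47, 1))) {
    i <- probe[1]; j <- probe[2]
    Xp <- X; Xp[i, j] <- Xp[i, j] + eps
    Xm <- X; Xm[i, j] <- Xm[i, j] - eps
    num <- (gcnForward(model, list(A), list(Xp)) -
              gcnForward(model, list(A), list(Xm))) / (2 * eps)
    expect_equal(sal[i, j], num,
                 tolerance = 1e-4 * max(1, abs(num)))
  }
})

test_that("integrated gradients are exact for linear maps and complete in general", {
  N <- 6
  A <- random_symmetric(N, seed = 92) + 0.1; diag(A) <- 0
  cvec <- c(1.5, -0.5, 2, 0, 0.25, -1)
  model <- linear_model(cvec, N, b = 0.3)
  X <- matrix(abs(rnorm(N, 2)), N, 1)
  ig <- integratedGradientsMap(model, list(A), list(X), steps = 10)[[1]]
  expect_equal(as.numeric(ig), cvec * as.numeric(X), tolerance = 1e-10)

  # completeness on a trained nonlinear model at 200 steps
  tm <- small_trained_model()
  m2 <- tm$fit
  A2 <- tm$ch$connectomes[[2]]
  X2 <- tm$X[[2]]
  f_x <- gcnForward(m2, list(A2), list(X2))
  f_b <- gcnForward(m2, list(A2), list(matrix(0, nrow(X2), ncol(X2))))
  ig200 <- integratedGradientsMap(m2, list(A2), list(X2), steps = 200)[[1]]
  expect_lt(abs(sum(ig200) - (f_x - f_b)), 1e-3 * max(1, abs(f_x - f_b)))

  # Riemann refinement: strong refinement shrinks the completeness residual
  # (rectifier kinks make the error O(1/steps), so only well-separated step
  # counts compare reliably)
  res_for <- function(s) {
    igs <- integratedGradientsMap(m2, list(A2), list(X2), steps = s)[[1]]
    abs(sum(igs) - (f_x - f_b))
  }
  expect_lt(res_for(200), res_for(4) / 2 + 1e-9)

  expect_error(integratedGradientsMap(m2, list(A2), list(X2), steps = 0),
               "at least 1")
})

test_that("a zero-feature region receives zero integrated-gradient attribution", {
  tm <- small_trained_model()
  model <- tm$fit
  A <- tm$ch$connectomes[[3]]
  X <- tm$X[[3]]
  X[10, ] <- 0
  ig <- integratedGradientsMap(model, list(A), list(X), steps = 20)[[1]]
  expect_equal(as.numeric(ig[10, ]), c(0, 0))
})

test_that("relevance aggregation follows magnitude and signed semantics", {
  ids <- sprintf("r%02d", 1:4)
  m1 <- matrix(c(1, -1, 0.5, 0), 4, 1)
  m2 <- matrix(c(-1, -1, 0.5, 0.2), 4, 1)

  agg_same <- aggregateRelevance(list(m1, m1), ids, method = "saliency")
  expect_equal(unname(relevanceWeights(agg_same)), abs(as.numeric(m1)))

  mag <- aggregateRelevance(list(m1, m2), ids, mode = "magnitude")
  expect_equal(unname(relevanceWeights(mag))[1], 1)     # |(+1)| and |(-1)| average to 1
  sgn <- aggregateRelevance(list(m1, m2), ids, mode = "signed")
  expect_equal(unname(relevanceWeights(sgn))[1], 0)     # +1 and -1 cancel

  set.seed(93)
  maps <- lapply(1:3, function(i) matrix(rnorm(8), 4, 2))
  agg <- aggregateRelevance(maps, ids, mode = "magnitude")
  oracle <- rowSums((abs(maps[[1]]) + abs(maps[[2]]) + abs(maps[[3]])) / 3)
  expect_equal(unname(relevanceWeights(agg)), oracle)
  # nested lists (per-fold collections) flatten transparently
  agg2 <- aggregateRelevance(list(maps[1:2], maps[3]), ids, mode = "magnitude")
  expect_equal(relevanceWeights(agg2), relevanceWeights(agg))

  expect_error(aggregateRelevance(list(m1, matrix(0, 3, 1)), ids), "identical")
})

test_that("top-fraction selection sizes, tie-breaks and intersections are deterministic", {
  w <- setNames(runif(148), sprintf("R%03d", 1:148))
  expect_length(topFractionRegions(w, 0.05), 8)      # ceil(7.4)
  ties <- setNames(rep(1, 10), sprintf("r%02d", 10:1))
  expect_equal(topFractionRegions(ties, 0.25), c("r01", "r02", "r03"))
  expect_equal(consistentRegions(list(c("a", "b", "c"), c("b", "c", "d"),
                                      c("c", "b"))), c("b", "c"))
  expect_error(topFractionRegions(w, 0), "fraction")
})

test_that("relevance maps export as ranked TSV tables", {
  ids <- sprintf("r%02d", 1:6)
  m <- matrix(c(0.1, 0.9, 0.3, 0.05, 0.6, 0.2), 6, 1)
  agg <- aggregateRelevance(list(m), ids)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRelevanceMap(agg, f, fraction = 1 / 3)
  tab <- read.delim(f)
  expect_equal(tab$region_id[1:2], c("r02", "r05"))
  expect_equal(sum(tab$selected_top), 2)
})
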