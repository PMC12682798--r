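test_that("simulated connectomes are valid with the planted block structure", {
  cfg <- simulationConfig(seed = 0, nRegions = 60)
  set.seed(100)
  for (i in 1:5) {
    C <- simulateConnectome(cfg, paste0("s", i))
    expect_true(validObject(C))
    expect_true(isNormalized(C))
    v <- connMatrix(C)
    expect_equal(sum(v[lower.tri(v)]), 1, tolerance = 1e-9)
    hemi <- hemispheres(C)
    iL <- hemi == "L"
    inter <- mean(v[iL, !iL])
    intra <- mean(c(v[iL, iL][upper.tri(v[iL, iL])],
                    v[!iL, !iL][upper.tri(v[!iL, !iL])]))
    expect_lt(inter, intra)
  }
})

test_that("noise-free weights decay with anterior-posterior distance", {
  # hubless configuration isolates the distance-decay law
  cfg <- simulationConfig(seed = 0, nRegions = 60, noiseSigma = 1e-9,
                          hubsPerHemisphere = 0)
  set.seed(101)
  C <- simulateConnectome(cfg, "nf")
  v <- connMatrix(C)
  for (i in c(1, 15, 30)) {
    cols <- setdiff(1:30, i)            # within the left hemisphere
    w <- v[i, cols][order(abs(cols - i))]
    expect_true(all(diff(w) < 1e-10))   # non-increasing with distance
  }
  # with hubs enabled, hub columns dominate distance at long range
  cfg2 <- simulationConfig(seed = 0, nRegions = 60, noiseSigma = 1e-9)
  set.seed(101)
  v2 <- connMatrix(simulateConnectome(cfg2, "nf2"))
  expect_gt(max(v2[1, 16:30]), max(v[1, 16:30]) * 1.5)
})

test_that("the group-level embedding reproduces the emulated gradient axes", {
  cfg <- simulationConfig(seed = 0, noiseSigma = 1e-9)
  set.seed(102)
  C <- simulateConnectome(cfg, "avg")
  g <- connectomeGradients(C)
  hemi <- hemispheres(C)
  pg <- gradientVectors(g)[, 1]
  # principal gradient separates hemispheres by sign
  expect_true(all(pg[hemi == "L"] * pg[hemi == "L"][1] > 0))
  expect_true(all(pg[hemi == "R"] * pg[hemi == "L"][1] < 0))
  # hemisphere-masked principal gradient tracks the planted A-P coordinate
  hg <- hemisphericGradients(C)
  pos <- (seq_len(74) - 1) / 73
  expect_gte(abs(cor(gradientVectors(hg$left)[, 1], pos)), 0.8)
})

test_that("synthetic IQ hits the instrument scale and planted effect size", {
  cfg <- simulationConfig(seed = 0)
  set.seed(103)
  pg <- matrix(rnorm(10000 * 148), 10000, 148,
               dimnames = list(NULL, GradIQ:::.sim_parcellation(148)@regionIds))
  iq <- simulateIQ(pg, cfg)
  expect_lt(abs(mean(iq) - 100), 0.5)
  expect_lt(abs(sd(iq) - 15), 0.5)

  # no-signal limit
  cfg0 <- simulationConfig(seed = 0, effectSize = 0)
  set.seed(104)
  iq0 <- simulateIQ(pg, cfg0)
  rr <- match(cfg0$relevantRegions, colnames(pg))
  sig <- rowMeans(pg[, rr])
  expect_lt(abs(cor(sig, iq0[, 1])), 0.05)

  # closed-form correlation of the additive model: cor = sqrt(effect size)
  set.seed(105)
  pg5 <- pg[1:5000, ]
  iq5 <- simulateIQ(pg5, cfg)
  sig5 <- rowMeans(pg5[, rr])
  expect_lt(abs(cor(sig5, iq5[, 1]) - sqrt(0.35)), 0.03)

  expect_error(simulateIQ(pg[, 1:10], cfg), "not in the parcellation")
})

test_that("planted batch effects behave as configured and ComBat removes them", {
  cfg <- simulationConfig(seed = 0, batchShift = 0.5, batchScale = 1)
  set.seed(106)
  x <- matrix(rnorm(1000 * 4), 1000, 4)
  batch <- rep(c("A", "B"), c(600, 400))   # B is the minority batch
  shifted <- addBatchEffects(x, batch, cfg)
  for (j in 1:4) {
    dm <- (mean(shifted[batch == "B", j]) - mean(shifted[batch == "A", j])) /
      sd(shifted[, j])
    expect_lt(abs(dm - 0.5), 0.15)
  }
  adj <- combatApply(combatFit(shifted, batch), shifted, batch)
  for (j in 1:4) {
    dm <- (mean(adj[batch == "B", j]) - mean(adj[batch == "A", j])) /
      sd(adj[, j])
    expect_lt(abs(dm), 0.1)
  }
  # identity configuration passes features through unchanged
  cfgid <- simulationConfig(seed = 0, batchShift = 0, batchScale = 1)
  expect_equal(addBatchEffects(x, batch, cfgid), x)
})

test_that("default cohorts reproduce the design margins deterministically", {
  coh <- small_cohort()
  expect_length(coh@connectomes, 40)
  expect_equal(dim(coh@features), c(60, 2, 40))

  # 67/33 split at n = 92 gives 62/30; check proportions at fixture scale
  tab <- sort(as.integer(table(coh@batch)), decreasing = TRUE)
  expect_equal(tab, c(27L, 13L))     # round(0.67 * 40), remainder

  # covariates in plausible printed ranges
  expect_lt(abs(mean(coh@covariates$ageAtScanMonths) - 12.95), 0.6)
  expect_true(sd(coh@covariates$ageAtScanMonths) > 0.5 &&
                sd(coh@covariates$ageAtScanMonths) < 1.5)
  expect_true(all(coh@covariates$nExcludedDWI >= 0))

  # byte-identical regeneration and export under the same seed
  cfg <- simulationConfig(seed = 3, nSubjects = 40, nRegions = 60,
                          nTemplateSubjects = 5)
  coh2 <- suppressWarnings(simulateCohort(cfg))
  expect_equal(coh@features, coh2@features)
  expect_identical(coh@iq, coh2@iq)
  expect_identical(coh@batch, coh2@batch)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  exportCohort(coh, d1); exportCohort(coh2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # ground truth sidecar exists but carries only planted metadata
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$effectSize, 0.35)
  expect_length(gt$relevantRegions, 5)
})

test_that("every cohort connectome passes full validation", {
  coh <- small_cohort()
  for (C in coh@connectomes[1:10]) {
    expect_true(validObject(C))
    v <- connMatrix(C)
    expect_true(all(v >= 0))
    expect_equal(v, t(v))
    expect_equal(sum(v[lower.tri(v)]), 1, tolerance = 1e-9)
  }
})
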