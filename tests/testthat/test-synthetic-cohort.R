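test_that("Delta-E is the CIE76 Euclidean distance and a metric", {
  expect_equal(computeDeltaE(c(50, 0, 0), c(50, 0, 0)), 0)
  expect_equal(computeDeltaE(c(50, 0, 0), c(50, 3, 4)), 5)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(3, sd = 30)
    b <- rnorm(3, sd = 30)
    expect_equal(computeDeltaE(a, b), computeDeltaE(b, a))
    expect_gte(computeDeltaE(a, b), 0)
  }
  expect_error(computeDeltaE(c(NA, 0, 0), c(1, 2, 3)), "finite")
})

test_that("cohort generation honors the shape contract and is deterministic", {
  spec <- CohortSpec(nSubjects = 52, seed = 7)
  coh1 <- generateCohort(spec)
  expect_equal(nrow(coh1$phenotypes), 52)
  expect_length(coh1$series, 52)
  expect_true(all(vapply(coh1$series, function(s)
    identical(dim(seriesData(s)), c(183L, 24L)), logical(1))))
  expect_true(all(vapply(coh1$motion, function(m)
    identical(dim(seriesData(m)), c(183L, 6L)), logical(1))))
  expect_equal(sum(coh1$phenotypes$group == "older"), 26)

  coh2 <- generateCohort(spec)
  expect_identical(coh1$phenotypes, coh2$phenotypes)
  expect_identical(seriesData(coh1$series[[5]]), seriesData(coh2$series[[5]]))
  expect_identical(seriesData(coh1$motion[[5]]), seriesData(coh2$motion[[5]]))
})

test_that("without couplings, slope or noise the MPI equals the intercept", {
  spec <- CohortSpec(nSubjects = 6, seed = 3, couplingPlan = list(),
                     behaviorNoiseSd = 0, ageMpiSlopeOlder = 0,
                     mpiIntercept = 73.3)
  coh <- generateCohort(spec)
  expect_equal(coh$phenotypes$mpi, rep(73.3, 6))
})

test_that("a non-PSD covariance design is rejected with the eigenvalue", {
  S <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3 and -1
  expect_error(
    generateSubjectTimeSeries(S, 100, 0, 2, 1, c("a", "b")),
    "positive semidefinite.*-1\\.0")
  expect_error(CohortSpec(nSubjects = 4, nodeLabels = c("a", "b"),
                          covarianceDesign = S),
               "positive semidefinite")
})

test_that("simulated series realize the planted covariance design", {
  # identity design, no autocorrelation: off-diagonal r within +/- 0.05
  I <- identityDesign(24)
  ts0 <- generateSubjectTimeSeries(I, 5000, 0, 2, seed = 7)
  R0 <- cor(seriesData(ts0))
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.05)

  # planted pair at 0.8 recovered within [0.75, 0.85]
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- 0.8
  ts1 <- generateSubjectTimeSeries(S, 5000, 0, 2, seed = 7,
                                   nodeLabels = letters[1:4])
  r12 <- cor(seriesData(ts1))[1, 2]
  expect_gt(r12, 0.75)
  expect_lt(r12, 0.85)

  # full default design: elementwise error < 0.06 at T = 5000
  D <- defaultCovarianceDesign()
  ts2 <- generateSubjectTimeSeries(D, 5000, 0.4, 2, seed = 7)
  expect_lt(max(abs(cor(seriesData(ts2)) - D)), 0.06)

  # lag-1 autocorrelation of every node close to the AR coefficient
  ac <- apply(seriesData(ts2), 2, function(x) cor(x[-1], x[-length(x)]))
  expect_true(all(abs(ac - 0.4) < 0.05))
})

test_that("a non-stationary AR coefficient is rejected", {
  expect_error(generateSubjectTimeSeries(diag(2), 100, 1, 2, 1, c("a", "b")),
               "non-stationary")
  expect_error(generateSubjectTimeSeries(diag(2), 100, 1.2, 2, 1, c("a", "b")),
               "non-stationary")
})

test_that("motion traces are zero-start random walks with the expected scale", {
  z <- generateMotionTrace(50, 0, 0, seed = 1)
  expect_true(all(seriesData(z) == 0))

  m1 <- generateMotionTrace(180, 0.05, 0.05, seed = 9)
  m2 <- generateMotionTrace(180, 0.05, 0.05, seed = 9)
  expect_identical(seriesData(m1), seriesData(m2))
  expect_true(all(seriesData(m1)[1, ] == 0))

  # half-normal scaling: mean step norm ~ 0.05 * E[chi_3] ~ 0.08
  md <- meanDisplacement(m1)
  expect_gt(md[["mean_translation_mm"]], 0)
  expect_lt(md[["mean_translation_mm"]], 0.2)

  expect_error(generateMotionTrace(50, -0.1, 0, seed = 1), "nonnegative")
})

test_that("rendered labelled volumes round-trip through ROI extraction", {
  ts <- generateSubjectTimeSeries(identityDesign(4, letters[1:4]), 30, 0.2,
                                  2, seed = 5, nodeLabels = letters[1:4])
  out <- renderLabelledVolume(ts, c(4, 2, 1), voxelsPerRoi = 2,
                              voxelNoiseSd = 0, seed = 1)
  back <- extractROITimeSeries(out$volume, out$labelMap, samplingInterval = 2)
  expect_equal(seriesData(back), seriesData(ts), tolerance = 1e-12)
  expect_identical(nodeLabels(back), letters[1:4])

  # one voxel per ROI
  out1 <- renderLabelledVolume(ts, c(2, 2, 1), voxelsPerRoi = 1)
  expect_equal(as.vector(table(out1$labelMap@grid)), rep(1L, 4))

  # noise averages out over many voxels: extracted ~ planted
  out2 <- renderLabelledVolume(ts, c(20, 20, 1), voxelsPerRoi = 100,
                               voxelNoiseSd = 1, seed = 2)
  back2 <- extractROITimeSeries(out2$volume, out2$labelMap)
  for (k in 1:4)
    expect_gt(cor(seriesData(back2)[, k], seriesData(ts)[, k]), 0.9)

  expect_error(renderLabelledVolume(ts, c(2, 1, 1), voxelsPerRoi = 2),
               "grid too small")
})

test_that("planted couplings appear in the ground-truth record and the MPI", {
  spec <- CohortSpec(
    nSubjects = 10, seed = 4,
    covarianceDesign = identityDesign(24),
    couplingPlan = list(list(target = "CAnt_L", coefficient = 2),
                        list(target = "M1_L|M1_R", coefficient = 3)),
    behaviorNoiseSd = 0, ageMpiSlopeOlder = 0, mpiIntercept = 70)
  coh <- generateCohort(spec)
  gt <- coh$groundTruth
  expect_equal(gt$couplings$target, c("CAnt_L", "M1_L|M1_R"))
  # MPI must equal intercept + coefficients x realized quantities exactly
  expect_equal(coh$phenotypes$mpi,
               70 + as.numeric(gt$realized %*% gt$couplings$coefficient))
  # realized quantities match recomputation from the band-limited series
  cm <- computeConnectivity(bandpassFilter(coh$series[[1]], 0.01, 0.08),
                            clip = TRUE)
  expect_equal(gt$realized[1, "CAnt_L"],
               sum(edgeWeights(cm)["CAnt_L", ]))
  i <- match("M1_L", nodeLabels(cm)); j <- match("M1_R", nodeLabels(cm))
  expect_equal(gt$realized[1, "M1_L|M1_R"], edgeWeights(cm)[i, j])
})
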