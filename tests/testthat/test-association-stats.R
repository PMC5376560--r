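# Independent oracle: partial correlation from the precision matrix of
# (x, y, covariates): r_xy.z = -Omega_xy / sqrt(Omega_xx * Omega_yy).
precisionPartialCor <- function(x, y, Z) {
  Omega <- solve(cor(cbind(x, y, Z)))
  -Omega[1, 2] / sqrt(Omega[1, 1] * Omega[2, 2])
}

test_that("partial correlation without covariates is the Pearson correlation", {
  set.seed(10)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  res <- partialCorrelation(x, y)
  ref <- pearsonCorrelation(x, y)
  expect_equal(res@rPartial, unname(cor(x, y)), tolerance = 1e-12)
  expect_equal(res@df, 28)
  expect_equal(res@pTwoTailed, ref$p_two_tailed, tolerance = 1e-12)
})

test_that("residualization agrees with the precision-matrix oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- 50
    Z <- matrix(rnorm(n * 2), n, 2)
    x <- Z %*% rnorm(2) + rnorm(n)
    y <- Z %*% rnorm(2) + 0.3 * x + rnorm(n)
    res <- partialCorrelation(x, y, Z)
    expect_equal(res@rPartial, precisionPartialCor(x, y, Z),
                 tolerance = 1e-10)
    # p recomputable from t and df
    expect_equal(res@pTwoTailed, 2 * pt(-abs(res@tStat), res@df),
                 tolerance = 1e-12)
    expect_equal(res@df, n - 2 - 2)
  }
})

test_that("partial correlation handles nulls and degenerate inputs", {
  set.seed(12)
  # y a pure function of covariates + noise, x independent: r ~ 0
  n <- 2000
  Z <- matrix(rnorm(n * 2), n, 2)
  y <- Z %*% c(1, -2) + rnorm(n)
  x <- rnorm(n)
  res <- partialCorrelation(x, y, Z)
  expect_lt(abs(res@rPartial), 0.05)

  # a pure-noise covariate barely moves the estimate at large n
  x2 <- rnorm(1000); y2 <- 0.5 * x2 + rnorm(1000)
  base <- partialCorrelation(x2, y2)
  noisy <- partialCorrelation(x2, y2, cbind(junk = rnorm(1000)))
  expect_lt(abs(noisy@rPartial - base@rPartial), 0.05)

  expect_error(partialCorrelation(1:3, 1:3), "at least")
  expect_error(partialCorrelation(rnorm(20), rnorm(20),
                                  cbind(a = rep(1, 20))),
               "rank deficient")
  z <- rnorm(20)
  expect_error(partialCorrelation(z, 2 * z + 3), "= 1")
})

test_that("median split assigns by the strict >/< rule and reports ties", {
  ph <- data.frame(subject_id = c("a", "b", "c", "d"), age = c(1, 2, 3, 4))
  sp <- medianSplit(ph)
  expect_equal(sp$threshold_age, 2.5)
  expect_equal(unname(sp$assignment), c("younger", "younger", "older", "older"))

  set.seed(13)
  ages <- c(runif(26, 55, 74), runif(26, 23, 54))
  ph52 <- data.frame(subject_id = sprintf("s%02d", 1:52), age = ages)
  sp52 <- medianSplit(ph52)
  expect_equal(sum(sp52$assignment == "older"), 26)
  expect_equal(sum(sp52$assignment == "younger"), 26)

  expect_error(medianSplit(data.frame(subject_id = c("a", "b"),
                                      age = c(5, 5))), "ties")
})

test_that("two-sample t agrees between raw and summary routes", {
  a <- c(0.1, 0.2, 0.15); res <- twoSampleT(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p_two_tailed, 1)

  set.seed(14)
  g1 <- rnorm(26, 70.5, 3.3); g2 <- rnorm(26, 73.3, 1.6)
  for (mode in c("welch", "pooled")) {
    raw <- twoSampleT(g1, g2, mode = mode)
    summ <- twoSampleT(mode = mode,
                       summaryA = c(mean(g1), sd(g1), 26),
                       summaryB = c(mean(g2), sd(g2), 26))
    expect_equal(raw$t, summ$t, tolerance = 1e-10)
    expect_equal(raw$df, summ$df, tolerance = 1e-10)
    expect_equal(raw$p_two_tailed, summ$p_two_tailed, tolerance = 1e-10)
  }

  # group MPI difference from the printed summaries: p < 0.001 both modes
  for (mode in c("welch", "pooled"))
    expect_lt(twoSampleT(mode = mode, summaryA = c(70.5, 3.3, 26),
                         summaryB = c(73.3, 1.6, 26))$p_two_tailed, 0.001)

  expect_error(twoSampleT(summaryA = c(1, 0, 26), summaryB = c(1, 1, 26)),
               "positive")
})

test_that("the 2x2 chi-square reproduces corrected and uncorrected forms", {
  counts <- matrix(c(7, 12, 19, 14), 2)  # rows: groups, cols: M / F
  res <- chiSquare2x2(counts)
  expect_equal(round(res$chi2, 2), 1.33)
  expect_equal(round(res$p_two_tailed, 2), 0.25)

  # hand-computed clamped Yates oracle
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  oracle <- sum(pmax(abs(counts - E) - 0.5, 0)^2 / E)
  expect_equal(res$chi2, oracle, tolerance = 1e-10)

  bal <- chiSquare2x2(matrix(10, 2, 2))
  expect_equal(bal$chi2, 0)
  expect_equal(bal$p_two_tailed, 1)

  expect_equal(round(chiSquare2x2(counts, continuityCorrection = FALSE)$chi2, 2),
               2.07)
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "positive")
})

test_that("Pearson correlation handles exact and planted relationships", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_error(pearsonCorrelation(x, rep(1, 5)), "zero variance")

  # planted within-older-group age decline recovered at n = 200
  coh <- generateCohort(CohortSpec(nSubjects = 200, seed = 7,
                                   nTimepoints = 20,
                                   couplingPlan = list(),
                                   ageMpiSlopeOlder = -0.25,
                                   behaviorNoiseSd = 1.5))
  older <- coh$phenotypes[coh$phenotypes$group == "older", ]
  res <- pearsonCorrelation(older$age, older$mpi)
  expect_lt(res$r, 0)
  expect_lt(res$p_two_tailed, 0.05)
})

test_that("hub identification recovers a planted coupling and stays exchangeable", {
  spec <- CohortSpec(nSubjects = 200, seed = 7,
                     covarianceDesign = identityDesign(24),
                     couplingPlan = list(list(target = "CAnt_L",
                                              coefficient = 6)),
                     behaviorNoiseSd = 0.3, ageMpiSlopeOlder = 0)
  coh <- generateCohort(spec)
  cms <- cohortConnectivity(coh)
  dc <- dcMatrix(cms)
  hubs <- identifyHubs(dc, coh$phenotypes)
  expect_equal(nrow(hubs), 24)
  planted <- hubs[hubs$label == "CAnt_L", ]
  expect_true(planted$is_hub)
  expect_gt(planted$r_partial, 0)
  expect_lt(planted$p, 0.05)
  # non-planted nodes flag at about the nominal rate
  expect_lte(mean(hubs$is_hub[hubs$label != "CAnt_L"]), 0.15)

  # permuting subjects jointly leaves the table unchanged
  perm <- sample(nrow(dc))
  hubsP <- identifyHubs(dc[perm, ], coh$phenotypes[perm, ])
  expect_equal(hubsP, hubs, tolerance = 1e-12)

  constant <- coh$phenotypes
  constant$mpi <- 70
  expect_error(identifyHubs(dc, constant), "variance")

  incomplete <- coh$phenotypes
  incomplete$age[3] <- NA
  expect_error(identifyHubs(dc, incomplete), "sub-003")
})

test_that("edge screening is uncorrected, complete, and recovers planted edges", {
  specNull <- CohortSpec(nSubjects = 200, seed = 7,
                         covarianceDesign = identityDesign(24),
                         behaviorNoiseSd = 1.5, ageMpiSlopeOlder = 0)
  cohNull <- generateCohort(specNull)
  cmsNull <- cohortConnectivity(cohNull)
  tabNull <- screenEdges(edgeWeightMatrix(cmsNull), cohNull$phenotypes)
  expect_equal(nrow(tabNull), 276)
  fp <- mean(tabNull$significant)
  expect_gte(fp, 0.02)
  expect_lte(fp, 0.09)
  # flags are exactly the uncorrected p < alpha rule
  expect_equal(tabNull$significant, tabNull$p < 0.05)

  specEdge <- CohortSpec(nSubjects = 200, seed = 7,
                         covarianceDesign = identityDesign(24),
                         couplingPlan = list(list(target = "M1_L|THA_R",
                                                  coefficient = 10)),
                         behaviorNoiseSd = 0.3, ageMpiSlopeOlder = 0)
  cohE <- generateCohort(specEdge)
  tabE <- screenEdges(edgeWeightMatrix(cohortConnectivity(cohE)),
                      cohE$phenotypes)
  expect_equal(tabE$label[which.min(tabE$p)], "M1_L|THA_R")
})

test_that("null hub and edge false positives stay in binomial bounds of alpha", {
  spec <- CohortSpec(nSubjects = 200, seed = 7,
                     covarianceDesign = identityDesign(24),
                     behaviorNoiseSd = 1.5, ageMpiSlopeOlder = 0)
  coh <- generateCohort(spec)
  cms <- cohortConnectivity(coh)
  hubP <- identifyHubs(dcMatrix(cms), coh$phenotypes)$p
  edgeP <- screenEdges(edgeWeightMatrix(cms), coh$phenotypes)$p
  # two-sided rejections at alpha = 0.05; binomial 95% bounds
  hubBounds <- qbinom(c(0.025, 0.975), 24, 0.05)
  expect_gte(sum(hubP < 0.05), hubBounds[1])
  expect_lte(sum(hubP < 0.05), hubBounds[2])
  edgeBounds <- qbinom(c(0.025, 0.975), 276, 0.05)
  expect_gte(sum(edgeP < 0.05), edgeBounds[1])
  expect_lte(sum(edgeP < 0.05), edgeBounds[2])
})
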