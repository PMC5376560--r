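test_that("discarding initial volumes trims rows and nothing else", {
  set.seed(1)
  ts <- makeSeries(matrix(rnorm(183 * 3), 183, 3))
  out <- discardInitialVolumes(ts, 3)
  expect_equal(nTimepoints(out), 180)
  expect_equal(seriesData(out), seriesData(ts)[-(1:3), ])

  same <- discardInitialVolumes(ts, 0)
  expect_equal(seriesData(same), seriesData(ts))

  tiny <- makeSeries(matrix(rnorm(9), 3, 3))
  expect_error(discardInitialVolumes(tiny, 3), "fewer than 2")
})

test_that("linear detrending removes exactly the least-squares line", {
  t <- 1:100
  line <- 2 * t + 5
  const <- rep(7, 100)
  set.seed(2)
  noise <- rnorm(100)
  ts <- makeSeries(cbind(line, const, noise))
  out <- seriesData(linearDetrend(ts))

  expect_lt(max(abs(out[, 1])), 1e-10)
  expect_lt(max(abs(out[, 2])), 1e-10)
  # third column differs from the input only by its own fitted line
  fit <- lm(noise ~ t)
  expect_equal(out[, 3], unname(residuals(fit)), tolerance = 1e-10)
  expect_lt(abs(mean(out[, 3])), 1e-12)

  expect_error(linearDetrend(makeSeries(matrix(rnorm(4), 2, 2))),
               "at least 3")
})

test_that("the ideal bandpass has unit in-band and zero out-of-band transfer", {
  n <- 1024; tr <- 2
  t <- (0:(n - 1)) * tr
  fIn <- 100 / (n * tr)   # ~0.0488 Hz, on the DFT grid, inside the band
  fOut <- 410 / (n * tr)  # ~0.2 Hz, on the grid, outside the band
  ts <- makeSeries(cbind(sin(2 * pi * fIn * t), sin(2 * pi * fOut * t),
                         rep(3, n)))
  out <- seriesData(bandpassFilter(ts, 0.01, 0.08))
  expect_lt(max(abs(out[, 1] - sin(2 * pi * fIn * t))), 0.01)
  expect_lt(max(abs(out[, 2])), 1e-8)
  expect_lt(max(abs(out[, 3])), 1e-8)  # DC removed

  # idempotent
  once <- bandpassFilter(ts, 0.01, 0.08)
  twice <- bandpassFilter(once, 0.01, 0.08)
  expect_equal(seriesData(twice), seriesData(once), tolerance = 1e-10)

  expect_error(bandpassFilter(ts, 0.01, 0.3), "Nyquist")
  expect_error(bandpassFilter(ts, 0.08, 0.01), "below")
})

test_that("nuisance regression matches an independent OLS solve", {
  set.seed(3)
  n <- 120
  R <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(rnorm(n * 4), n, 4)
  Y[, 1] <- R[, 2]  # perfectly explained column
  ts <- makeSeries(Y)
  out <- seriesData(nuisanceRegress(ts, NuisanceSet(R, c("a", "b", "c"))))

  expect_lt(max(abs(out[, 1])), 1e-10)
  # brute-force normal-equations oracle
  X <- cbind(1, R)
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(out, unname(Y - X %*% beta), tolerance = 1e-8,
               ignore_attr = TRUE)
  # residuals orthogonal to every regressor, zero mean
  for (j in 1:3)
    expect_lt(max(abs(crossprod(R[, j], out))) /
                (sqrt(sum(R[, j]^2)) * max(sqrt(colSums(out^2)))), 1e-8)
  expect_lt(max(abs(colMeans(out))), 1e-12)
})

test_that("constant regressors demean; true collinearity is an error", {
  set.seed(4)
  Y <- matrix(rnorm(60), 30, 2)
  ts <- makeSeries(Y)
  # a single constant regressor is absorbed by the intercept -> demeaning
  out <- seriesData(nuisanceRegress(ts, NuisanceSet(matrix(5, 30, 1), "const")))
  expect_equal(out, scale(Y, scale = FALSE), tolerance = 1e-10,
               ignore_attr = TRUE)

  R <- cbind(a = rnorm(30))
  R <- cbind(R, dup = 2 * R[, 1])
  expect_error(nuisanceRegress(ts, NuisanceSet(R)), "rank deficient.*dup")

  expect_error(NuisanceSet(matrix(numeric(0), 30, 0)), "at least one")
})

test_that("the fixed preprocessing order is enforced", {
  set.seed(5)
  ts <- makeSeries(matrix(rnorm(100 * 2), 100, 2))
  bp <- bandpassFilter(ts, 0.01, 0.08)
  expect_error(linearDetrend(bp), "out of order")
  expect_error(discardInitialVolumes(bp, 3), "out of order")
  nr <- nuisanceRegress(ts, NuisanceSet(cbind(x = rnorm(100))))
  expect_error(bandpassFilter(nr, 0.01, 0.08), "out of order")

  full <- preprocessSeries(makeSeries(matrix(rnorm(183 * 2), 183, 2)),
                           NuisanceSet(cbind(x = rnorm(183))))
  expect_identical(processingSteps(full),
                   c("discard", "detrend", "bandpass", "nuisance"))
  expect_equal(nTimepoints(full), 180)
})

test_that("ROI extraction averages voxels exactly", {
  # all voxels of a label share v(t) -> column equals v(t); mixed values average
  grid <- array(c(1L, 1L, 2L, 0L), c(4, 1, 1))
  lm <- LabelMap(grid, c("1" = "A", "2" = "B"))
  vol <- array(0, c(4, 1, 1, 3))
  vol[1, 1, 1, ] <- c(1, 5, 9)
  vol[2, 1, 1, ] <- c(3, 5, 9)
  vol[3, 1, 1, ] <- c(7, 8, 9)
  out <- extractROITimeSeries(vol, lm)
  expect_equal(seriesData(out)[, "A"], c(2, 5, 9))
  expect_equal(seriesData(out)[, "B"], c(7, 8, 9))

  # brute-force loop oracle on a random volume
  set.seed(6)
  grid2 <- array(sample(0:3, 60, replace = TRUE), c(5, 4, 3))
  grid2[1:3] <- 1:3  # ensure every label occupied
  lm2 <- LabelMap(grid2, c("1" = "r1", "2" = "r2", "3" = "r3"))
  vol2 <- array(rnorm(60 * 7), c(5, 4, 3, 7))
  out2 <- seriesData(extractROITimeSeries(vol2, lm2))
  for (k in 1:3) for (t in 1:7) {
    acc <- 0; cnt <- 0
    for (i in 1:5) for (j in 1:4) for (l in 1:3)
      if (grid2[i, j, l] == k) { acc <- acc + vol2[i, j, l, t]; cnt <- cnt + 1 }
    expect_equal(unname(out2[t, k]), acc / cnt, tolerance = 1e-12)
  }

  lm3 <- LabelMap(grid, c("1" = "A", "2" = "B", "9" = "ghost"))
  expect_error(extractROITimeSeries(vol, lm3), "ghost")
})

test_that("probabilistic-map thresholding uses an inclusive boundary", {
  expect_true(all(thresholdProbabilisticMap(array(0.6, c(2, 2, 2))) == 1))
  expect_true(all(thresholdProbabilisticMap(array(0.4, c(2, 2, 2))) == 0))
  expect_equal(as.vector(thresholdProbabilisticMap(array(c(0.5, 0.49), c(2, 1, 1)))),
               c(1L, 0L))
  expect_error(thresholdProbabilisticMap(array(1.2, c(1, 1, 1))), "\\[0, 1\\]")
})
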