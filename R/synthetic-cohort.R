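#' Colorimetric masticatory performance (Delta-E, CIE76)
#'
#' Masticatory performance is scored by chewing a color-changeable gum and
#' measuring the color change of the flattened bolus in the CIE L*a*b*
#' system. This computes the CIE76 color difference
#' `sqrt((dL)^2 + (da)^2 + (db)^2)` between two Lab readings.
#'
#' @param before,after numeric length-3 vectors `c(L, a, b)`.
#' @return Nonnegative scalar Delta-E; symmetric in its arguments, zero iff
#'   the two colors are identical.
#' @examples
#' computeDeltaE(c(50, 0, 0), c(50, 3, 4))  # 5
#' @export
computeDeltaE <- function(before, after) {
  before <- as.numeric(before)
  after <- as.numeric(after)
  if (length(before) != 3 || length(after) != 3)
    stop("Lab colors must have exactly 3 components (L, a, b)")
  if (!all(is.finite(before)) || !all(is.finite(after)))
    stop("Lab color components must be finite")
  sqrt(sum((after - before)^2))
}

.symmetricSqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

.checkPSD <- function(S, what = "covarianceDesign") {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("'%s' is not positive semidefinite (smallest eigenvalue %.3e)",
                 what, min(ev)))
  invisible(ev)
}

#' Simulate one subject's regional BOLD-like time series
#'
#' Gaussian AR(1) innovations with stationary unit marginal variance are
#' colored by the symmetric square root of the target correlation matrix,
#' so that the sample inter-node correlation converges to
#' `covarianceDesign` and every node's lag-1 autocorrelation converges to
#' `arCoefficient` as the series lengthens.
#'
#' @param covarianceDesign symmetric unit-diagonal PSD target correlation
#'   matrix (node x node).
#' @param nTimepoints series length, at least 10.
#' @param arCoefficient lag-1 autocorrelation in [0, 1); values >= 1 are
#'   rejected as non-stationary.
#' @param samplingInterval TR in seconds.
#' @param seed integer seed; fixed seed gives a bit-identical series.
#' @param nodeLabels node names; defaults to the design's column names.
#' @return An [ROITimeSeries-class].
#' @examples
#' ts <- generateSubjectTimeSeries(diag(3), 100, 0.3, 2, seed = 1,
#'                                 nodeLabels = c("A", "B", "C"))
#' dim(seriesData(ts))
#' @export
generateSubjectTimeSeries <- function(covarianceDesign, nTimepoints,
                                      arCoefficient = 0,
                                      samplingInterval = 2, seed = 1,
                                      nodeLabels = colnames(covarianceDesign)) {
  if (nTimepoints < 10)
    stop("'nTimepoints' must be at least 10")
  if (arCoefficient >= 1)
    stop("'arCoefficient' must be < 1 (the AR(1) process is non-stationary otherwise)")
  if (arCoefficient < 0)
    stop("'arCoefficient' must be nonnegative")
  covarianceDesign <- as.matrix(covarianceDesign)
  .checkPSD(covarianceDesign)
  p <- ncol(covarianceDesign)
  if (is.null(nodeLabels)) nodeLabels <- paste0("node", seq_len(p))
  sqrtS <- .symmetricSqrt(covarianceDesign)
  set.seed(seed)
  innov <- matrix(stats::rnorm(nTimepoints * p), nTimepoints, p)
  u0 <- stats::rnorm(p)  # stationary start, unit variance
  if (arCoefficient > 0) {
    s <- sqrt(1 - arCoefficient^2)
    U <- vapply(seq_len(p), function(j) {
      as.numeric(stats::filter(s * innov[, j], arCoefficient,
                               method = "recursive", init = u0[j]))
    }, numeric(nTimepoints))
  } else {
    U <- innov
  }
  ROITimeSeries(U %*% sqrtS, nodeLabels = nodeLabels,
                samplingInterval = samplingInterval)
}

#' Simulate a head-motion trace
#'
#' A cumulative Gaussian random walk in all six rigid-body parameters,
#' starting at zero. Translations (mm) and rotations (degrees) use separate
#' per-frame step standard deviations.
#'
#' @param nTimepoints number of volumes (rows).
#' @param stepSdMm per-frame step SD of each translation axis, in mm.
#' @param stepSdDeg per-frame step SD of each rotation axis, in degrees.
#' @param seed integer seed.
#' @return A [MotionTrace-class] with `nTimepoints` rows.
#' @examples
#' tr <- generateMotionTrace(183, 0.02, 0.02, seed = 1)
#' meanDisplacement(tr)
#' @export
generateMotionTrace <- function(nTimepoints, stepSdMm = 0.02,
                                stepSdDeg = 0.02, seed = 1) {
  if (stepSdMm < 0 || stepSdDeg < 0)
    stop("motion step standard deviations must be nonnegative")
  if (nTimepoints < 2)
    stop("'nTimepoints' must be at least 2")
  set.seed(seed)
  sds <- rep(c(stepSdMm, stepSdDeg), each = 3)
  steps <- matrix(stats::rnorm(6 * (nTimepoints - 1)), nTimepoints - 1, 6)
  steps <- sweep(steps, 2, sds, `*`)
  MotionTrace(rbind(0, apply(steps, 2, cumsum)))
}

.generateNuisanceSignals <- function(nTimepoints, seed, ar = 0.4) {
  set.seed(seed)
  s <- sqrt(1 - ar^2)
  sig <- vapply(1:2, function(j) {
    as.numeric(stats::filter(s * stats::rnorm(nTimepoints), ar,
                             method = "recursive",
                             init = stats::rnorm(1)))
  }, numeric(nTimepoints))
  colnames(sig) <- c("ventricle", "white_matter")
  sig
}

#' Render a labelled 4-D volume from an ROI time series
#'
#' Produces a toy 4-D acquisition in which every voxel carrying label k
#' holds node k's signal plus independent Gaussian noise; label 0 marks
#' background voxels (constant zero). With `voxelNoiseSd = 0`,
#' [extractROITimeSeries()] on the result reproduces the input series
#' exactly.
#'
#' @param roiTs an [ROITimeSeries-class].
#' @param gridShape length-3 integer vector of spatial dimensions; its
#'   product must be at least `nodes * voxelsPerRoi`.
#' @param voxelsPerRoi voxels assigned to each ROI.
#' @param voxelNoiseSd SD of the per-voxel additive noise.
#' @param seed integer seed.
#' @return A list with `volume` (4-D array, spatial dims then time) and
#'   `labelMap` (a [LabelMap-class]).
#' @examples
#' ts <- generateSubjectTimeSeries(diag(2), 20, 0, 2, 1, c("A", "B"))
#' out <- renderLabelledVolume(ts, c(2, 2, 1), voxelsPerRoi = 1)
#' table(out$labelMap@grid)
#' @export
renderLabelledVolume <- function(roiTs, gridShape, voxelsPerRoi = 1,
                                 voxelNoiseSd = 0, seed = 1) {
  stopifnot(is(roiTs, "ROITimeSeries"))
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3)
    stop("'gridShape' must have 3 dimensions")
  p <- ncol(roiTs@data)
  nT <- nrow(roiTs@data)
  nVox <- prod(gridShape)
  needed <- p * voxelsPerRoi
  if (nVox < needed)
    stop(sprintf("grid too small: %d voxels available, %d required (%d nodes x %d voxels)",
                 nVox, needed, p, voxelsPerRoi))
  set.seed(seed)
  labels <- integer(nVox)
  mat <- matrix(0, nVox, nT)
  for (k in seq_len(p)) {
    idx <- ((k - 1) * voxelsPerRoi + 1):(k * voxelsPerRoi)
    labels[idx] <- k
    block <- matrix(roiTs@data[, k], voxelsPerRoi, nT, byrow = TRUE)
    if (voxelNoiseSd > 0)
      block <- block + matrix(stats::rnorm(voxelsPerRoi * nT, sd = voxelNoiseSd),
                              voxelsPerRoi, nT)
    mat[idx, ] <- block
  }
  list(
    volume = array(mat, c(gridShape, nT)),
    labelMap = LabelMap(array(labels, gridShape),
                        stats::setNames(roiTs@nodeLabels,
                                        as.character(seq_len(p))))
  )
}

.realizedCouplingValues <- function(cm, targets) {
  dc <- NULL
  vapply(targets, function(tg) {
    if (grepl("|", tg, fixed = TRUE)) {
      nodes <- strsplit(tg, "|", fixed = TRUE)[[1]]
      i <- match(nodes[1], cm@nodeLabels)
      j <- match(nodes[2], cm@nodeLabels)
      if (is.na(i) || is.na(j))
        stop(sprintf("coupling target edge '%s' names unknown nodes", tg))
      cm@weight[i, j]
    } else {
      k <- match(tg, cm@nodeLabels)
      if (is.na(k))
        stop(sprintf("coupling target node '%s' is not a node label", tg))
      sum(cm@weight[k, ])
    }
  }, numeric(1))
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Simulates, for every subject: a regional time series realizing the
#' specified correlation design, a motion trace, ventricle/white-matter
#' nuisance signals, and a phenotype record (age drawn uniformly within the
#' group's age range, gender, group, MPI). The MPI is built as
#' `intercept + sum(coefficient * realized quantity) + age trend + noise`,
#' where the realized quantities are the subject's degree centralities or
#' edge weights computed from the band-limited (0.01-0.08 Hz) component of
#' the simulated series — the intrinsic low-frequency connectivity the
#' downstream pipeline estimates — and the age trend
#' `ageMpiSlopeOlder * (age - boundary)` applies within the older group
#' only. Every planted quantity is returned in the ground-truth record.
#'
#' @param spec a [CohortSpec-class].
#' @return A list with elements `phenotypes` (data.frame with columns
#'   subject_id, age, gender, group, mpi), `series`, `motion`, `nuisance`
#'   (named lists keyed by subject id), and `groundTruth` (a list recording
#'   the planted couplings, per-subject realized values, intercept, age
#'   boundary and slope, and the per-subject seeds).
#' @examples
#' coh <- generateCohort(CohortSpec(nSubjects = 4, seed = 1))
#' coh$phenotypes
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- as.integer(spec@nSubjects)
  set.seed(as.integer(spec@seed))
  maxSeed <- 2147483646L
  tsSeeds <- sample.int(maxSeed, n)
  motionSeeds <- sample.int(maxSeed, n)
  nuisanceSeeds <- sample.int(maxSeed, n)

  nOlder <- n %/% 2
  group <- c(rep("older", nOlder), rep("younger", n - nOlder))
  ages <- numeric(n)
  ages[group == "older"] <- stats::runif(nOlder, spec@ageRangeOlder[1],
                                         spec@ageRangeOlder[2])
  ages[group == "younger"] <- stats::runif(n - nOlder,
                                           spec@ageRangeYounger[1],
                                           spec@ageRangeYounger[2])
  gender <- ifelse(stats::runif(n) < spec@maleProportion, "M", "F")
  mpiNoise <- stats::rnorm(n, 0, spec@behaviorNoiseSd)

  ids <- sprintf("sub-%03d", seq_len(n))
  series <- vector("list", n)
  motion <- vector("list", n)
  nuisance <- vector("list", n)
  targets <- vapply(spec@couplingPlan, function(cp) as.character(cp$target),
                    character(1))
  coefs <- vapply(spec@couplingPlan, function(cp) as.numeric(cp$coefficient),
                  numeric(1))
  realized <- matrix(NA_real_, n, length(targets),
                     dimnames = list(ids, targets))

  for (i in seq_len(n)) {
    series[[i]] <- generateSubjectTimeSeries(
      spec@covarianceDesign, spec@nTimepoints, spec@arCoefficient,
      spec@samplingInterval, seed = tsSeeds[i],
      nodeLabels = spec@nodeLabels)
    motion[[i]] <- generateMotionTrace(spec@nTimepoints, spec@stepSdMm,
                                       spec@stepSdDeg, seed = motionSeeds[i])
    nuisance[[i]] <- .generateNuisanceSignals(spec@nTimepoints,
                                              seed = nuisanceSeeds[i])
    if (length(targets)) {
      filtered <- bandpassFilter(series[[i]], 0.01, 0.08)
      cm <- computeConnectivity(filtered, clip = TRUE)
      realized[i, ] <- .realizedCouplingValues(cm, targets)
    }
  }
  names(series) <- names(motion) <- names(nuisance) <- ids

  ageBoundary <- (max(spec@ageRangeYounger) + min(spec@ageRangeOlder)) / 2
  ageTrend <- ifelse(group == "older",
                     spec@ageMpiSlopeOlder * (ages - ageBoundary), 0)
  coupled <- if (length(targets)) as.numeric(realized %*% coefs) else 0
  mpi <- spec@mpiIntercept + coupled + ageTrend + mpiNoise

  phenotypes <- data.frame(
    subject_id = ids, age = ages, gender = gender, group = group,
    mpi = mpi, stringsAsFactors = FALSE)

  list(
    phenotypes = phenotypes,
    series = series,
    motion = motion,
    nuisance = nuisance,
    groundTruth = list(
      couplings = data.frame(target = targets, coefficient = coefs,
                             stringsAsFactors = FALSE),
      realized = realized,
      mpiIntercept = spec@mpiIntercept,
      ageBoundary = ageBoundary,
      ageMpiSlopeOlder = spec@ageMpiSlopeOlder,
      behaviorNoiseSd = spec@behaviorNoiseSd,
      seed = spec@seed,
      subjectSeeds = list(series = tsSeeds, motion = motionSeeds,
                          nuisance = nuisanceSeeds)
    )
  )
}
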