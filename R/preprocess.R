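.stageOrder <- c(discard = 1L, detrend = 2L, bandpass = 3L, nuisance = 4L)

# The preprocessing order is fixed: discard -> detrend -> bandpass ->
# nuisance regression. A stage may be applied standalone or repeated, but
# never after a later stage.
.checkStage <- function(series, stage) {
  applied <- series@steps
  late <- applied[.stageOrder[applied] > .stageOrder[[stage]]]
  if (length(late))
    stop(sprintf("preprocessing out of order: cannot apply '%s' after '%s'",
                 stage, late[1]))
  invisible(TRUE)
}

.withStage <- function(series, data, stage) {
  out <- series
  out@data <- data
  colnames(out@data) <- out@nodeLabels
  out@steps <- c(series@steps, stage)
  validObject(out)
  out
}

#' Discard initial volumes
#'
#' Drops the first `nDiscard` volumes (magnetic-saturation dummies; three
#' in a standard 183-volume acquisition, leaving 180). Remaining rows are
#' unchanged.
#'
#' @param series an [ROITimeSeries-class].
#' @param nDiscard nonnegative integer; must leave at least 2 timepoints.
#' @return The trimmed [ROITimeSeries-class].
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(183 * 2), 183, 2), c("A", "B"), 2)
#' nTimepoints(discardInitialVolumes(ts, 3))  # 180
#' @export
discardInitialVolumes <- function(series, nDiscard = 3) {
  stopifnot(is(series, "ROITimeSeries"))
  .checkStage(series, "discard")
  if (nDiscard < 0) stop("'nDiscard' must be nonnegative")
  if (nDiscard >= nrow(series@data) - 1)
    stop(sprintf("discarding %d of %d timepoints leaves fewer than 2",
                 nDiscard, nrow(series@data)))
  keep <- if (nDiscard > 0) -(seq_len(nDiscard)) else TRUE
  .withStage(series, series@data[keep, , drop = FALSE], "discard")
}

#' Remove the linear trend from every node
#'
#' Least-squares removal of an intercept and linear slope per column; the
#' output columns have exactly zero mean and zero linear trend.
#'
#' @param series an [ROITimeSeries-class] with at least 3 timepoints.
#' @return The detrended [ROITimeSeries-class].
#' @export
linearDetrend <- function(series) {
  stopifnot(is(series, "ROITimeSeries"))
  .checkStage(series, "detrend")
  n <- nrow(series@data)
  if (n < 3) stop("detrending needs at least 3 timepoints")
  X <- cbind(1, seq_len(n))
  .withStage(series, qr.resid(qr(X), series@data), "detrend")
}

#' Ideal frequency-domain bandpass filter
#'
#' Rectangular filter on the discrete Fourier transform: coefficients whose
#' frequency lies in `[lowHz, highHz]` (boundaries inclusive) are kept,
#' all others — including the zero-frequency mean unless `lowHz = 0` — are
#' zeroed, and the inverse transform is returned. Defaults isolate the
#' 0.01-0.08 Hz band in which intrinsic connectivity fluctuations live.
#' The filter is idempotent.
#'
#' @param series an [ROITimeSeries-class].
#' @param lowHz,highHz band edges in Hz; requires
#'   `0 <= lowHz < highHz <= 1 / (2 * samplingInterval)` (Nyquist).
#' @return The filtered [ROITimeSeries-class] (real-valued).
#' @export
bandpassFilter <- function(series, lowHz = 0.01, highHz = 0.08) {
  stopifnot(is(series, "ROITimeSeries"))
  .checkStage(series, "bandpass")
  tr <- series@samplingInterval
  nyquist <- 1 / (2 * tr)
  if (lowHz < 0) stop("'lowHz' must be nonnegative")
  if (lowHz >= highHz) stop("'lowHz' must be below 'highHz'")
  if (highHz > nyquist + 1e-12)
    stop(sprintf("'highHz' (%g Hz) exceeds the Nyquist frequency (%g Hz)",
                 highHz, nyquist))
  n <- nrow(series@data)
  freq <- (seq_len(n) - 1) / (n * tr)
  folded <- pmin(freq, 1 / tr - freq)
  keep <- folded >= lowHz & folded <= highHz
  Y <- stats::mvfft(series@data)
  Y[!keep, ] <- 0
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  .withStage(series, out, "bandpass")
}

#' Regress nuisance signals out of every node
#'
#' Ordinary least squares of each node series on an intercept plus the
#' nuisance regressors (six motion parameters, mean ventricle signal, mean
#' deep-white-matter signal); the residuals are returned. The whole-brain
#' global signal is deliberately not part of the standard regressor set.
#' Residuals are orthogonal to every regressor and have zero mean.
#'
#' Constant regressors are absorbed by the intercept and dropped; any other
#' rank deficiency is an error naming the offending regressor.
#'
#' @param series an [ROITimeSeries-class].
#' @param nuisance a [NuisanceSet-class] with the same number of timepoints.
#' @return The residual [ROITimeSeries-class].
#' @export
nuisanceRegress <- function(series, nuisance) {
  stopifnot(is(series, "ROITimeSeries"), is(nuisance, "NuisanceSet"))
  .checkStage(series, "nuisance")
  R <- nuisance@regressors
  if (nrow(R) != nrow(series@data))
    stop(sprintf("nuisance set has %d timepoints but the series has %d",
                 nrow(R), nrow(series@data)))
  constant <- apply(R, 2, function(col) max(col) - min(col) == 0)
  R <- R[, !constant, drop = FALSE]
  X <- cbind(intercept = rep(1, nrow(R)), R)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop(sprintf("nuisance design is rank deficient: regressor '%s' is collinear",
                 colnames(X)[dropped[1]]))
  }
  .withStage(series, qr.resid(qrX, series@data), "nuisance")
}

#' Mean regional time series from a labelled 4-D volume
#'
#' For each ROI in the label map, the unweighted mean over that ROI's
#' voxels is taken at every timepoint. Columns are ordered by increasing
#' integer label and named by the label names.
#'
#' @param volume 4-D numeric array, spatial dimensions then time.
#' @param labelMap a [LabelMap-class] matching the volume's spatial shape.
#' @param samplingInterval TR in seconds for the returned series.
#' @return An [ROITimeSeries-class] with one column per labelled ROI.
#' @export
extractROITimeSeries <- function(volume, labelMap, samplingInterval = 2) {
  stopifnot(is(labelMap, "LabelMap"))
  d <- dim(volume)
  if (length(d) != 4)
    stop("'volume' must be a 4-D array (x, y, z, time)")
  if (!identical(d[1:3], dim(labelMap@grid)))
    stop("spatial dimensions of 'volume' and 'labelMap' differ")
  nT <- d[4]
  lab <- as.vector(labelMap@grid)
  mat <- matrix(volume, prod(d[1:3]), nT)
  ids <- sort(as.integer(names(labelMap@labelNames)))
  cols <- vapply(ids, function(k) {
    rows <- lab == k
    if (!any(rows))
      stop(sprintf("ROI label %d ('%s') has no voxels in the label map",
                   k, labelMap@labelNames[[as.character(k)]]))
    colMeans(mat[rows, , drop = FALSE])
  }, numeric(nT))
  ROITimeSeries(cols,
                nodeLabels = unname(labelMap@labelNames[as.character(ids)]),
                samplingInterval = samplingInterval)
}

#' Threshold a probabilistic ROI map into a binary mask
#'
#' A voxel enters the mask iff its probability is greater than or equal to
#' the threshold (inclusive boundary: a voxel at exactly the group
#' threshold of 0.5 is included).
#'
#' @param prob numeric array with values in [0, 1].
#' @param threshold inclusion threshold, default 0.5.
#' @return An integer array of 0/1 with the same shape.
#' @export
thresholdProbabilisticMap <- function(prob, threshold = 0.5) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1))
    stop("probabilistic map values must lie in [0, 1]")
  mask <- array(as.integer(prob >= threshold), dim(prob))
  mask
}

#' Run the fixed preprocessing pipeline on one series
#'
#' Applies, in order: initial-volume discard, linear detrending, ideal
#' bandpass filtering, and nuisance regression. The nuisance regressors
#' must already match the post-discard length (or, if they match the
#' original length, their first `nDiscard` rows are dropped to stay
#' aligned). By default the regressors are used as supplied;
#' `filterNuisance = TRUE` bandpasses them to the same band first.
#'
#' @param series raw [ROITimeSeries-class].
#' @param nuisance a [NuisanceSet-class] (or NULL to skip regression).
#' @param nDiscard initial volumes to drop (default 3).
#' @param lowHz,highHz band edges in Hz.
#' @param filterNuisance logical; bandpass the regressors before the
#'   regression (default FALSE).
#' @return The fully preprocessed [ROITimeSeries-class].
#' @export
preprocessSeries <- function(series, nuisance = NULL, nDiscard = 3,
                             lowHz = 0.01, highHz = 0.08,
                             filterNuisance = FALSE) {
  out <- discardInitialVolumes(series, nDiscard)
  out <- linearDetrend(out)
  out <- bandpassFilter(out, lowHz, highHz)
  if (!is.null(nuisance)) {
    R <- nuisance@regressors
    if (nrow(R) == nTimepoints(series) && nDiscard > 0)
      R <- R[-seq_len(nDiscard), , drop = FALSE]
    if (filterNuisance) {
      rser <- ROITimeSeries(R, nodeLabels = nuisance@names,
                            samplingInterval = series@samplingInterval)
      R <- seriesData(bandpassFilter(rser, lowHz, highHz))
    }
    out <- nuisanceRegress(out, NuisanceSet(R, nuisance@names))
  }
  out
}
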