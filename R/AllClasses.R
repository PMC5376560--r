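#' @import methods
NULL

.isFiniteNumericMatrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x))
}

#' Regional BOLD-like time series
#'
#' A timepoints x nodes matrix of regional mean signals together with the
#' node labels and the sampling interval (the repetition time, TR). The
#' `steps` slot records which preprocessing stages have been applied, in
#' order, so that the fixed pipeline order (discard, detrend, bandpass,
#' nuisance regression) can be enforced.
#'
#' @slot data numeric matrix, timepoints x nodes, all entries finite.
#' @slot nodeLabels character vector of distinct node names, one per column.
#' @slot samplingInterval positive scalar, the sampling interval in seconds.
#' @slot steps character vector of preprocessing stages applied so far.
#'
#' @seealso [ROITimeSeries()] for the constructor.
#' @exportClass ROITimeSeries
setClass("ROITimeSeries",
  representation(
    data = "matrix",
    nodeLabels = "character",
    samplingInterval = "numeric",
    steps = "character"
  ),
  prototype(steps = character())
)

setValidity("ROITimeSeries", function(object) {
  msg <- character()
  if (!.isFiniteNumericMatrix(object@data))
    msg <- c(msg, "'data' must be a numeric matrix with all entries finite")
  else {
    if (nrow(object@data) < 2)
      msg <- c(msg, "a time series needs at least 2 timepoints")
    if (ncol(object@data) != length(object@nodeLabels))
      msg <- c(msg, "length of 'nodeLabels' must equal the number of columns")
  }
  if (anyDuplicated(object@nodeLabels))
    msg <- c(msg, "'nodeLabels' must be distinct")
  if (length(object@samplingInterval) != 1 ||
      !is.finite(object@samplingInterval) || object@samplingInterval <= 0)
    msg <- c(msg, "'samplingInterval' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an ROITimeSeries
#'
#' @param data timepoints x nodes numeric matrix.
#' @param nodeLabels character vector of node names; defaults to the column
#'   names of `data`.
#' @param samplingInterval sampling interval (TR) in seconds.
#' @param steps preprocessing stages already applied (normally empty).
#' @return An [ROITimeSeries-class] object.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(40), 20, 2), c("A", "B"), 2)
#' nTimepoints(ts)
#' @export
ROITimeSeries <- function(data, nodeLabels = colnames(data),
                          samplingInterval = 2, steps = character()) {
  data <- as.matrix(data)
  if (is.null(nodeLabels))
    nodeLabels <- paste0("node", seq_len(ncol(data)))
  colnames(data) <- nodeLabels
  new("ROITimeSeries", data = data, nodeLabels = as.character(nodeLabels),
      samplingInterval = as.numeric(samplingInterval), steps = steps)
}

#' Head-motion trace
#'
#' Timepoints x 6 rigid-body realignment parameters: three translations
#' (tx, ty, tz, in mm) followed by three rotations (rx, ry, rz, in degrees).
#'
#' @slot data numeric matrix with 6 columns, all entries finite.
#' @seealso [MotionTrace()], [meanDisplacement()], [checkExclusion()].
#' @exportClass MotionTrace
setClass("MotionTrace", representation(data = "matrix"))

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (!.isFiniteNumericMatrix(object@data))
    msg <- c(msg, "'data' must be a numeric matrix with all entries finite")
  else {
    if (ncol(object@data) != 6)
      msg <- c(msg, "a motion trace has exactly 6 columns (tx ty tz rx ry rz)")
    if (nrow(object@data) < 2)
      msg <- c(msg, "a motion trace needs at least 2 timepoints")
  }
  if (length(msg)) msg else TRUE
})

.motionColumns <- c("tx", "ty", "tz", "rx", "ry", "rz")

#' Construct a MotionTrace
#'
#' @param data timepoints x 6 numeric matrix (tx ty tz in mm, rx ry rz in
#'   degrees).
#' @return A [MotionTrace-class] object.
#' @export
MotionTrace <- function(data) {
  data <- as.matrix(data)
  colnames(data) <- .motionColumns
  new("MotionTrace", data = data)
}

#' Nuisance regressor set
#'
#' Confound signals regressed out of every node time series: typically the
#' six motion parameters plus mean ventricle and deep-white-matter signals.
#' An intercept is always added by [nuisanceRegress()]; the set itself must
#' contain at least one regressor.
#'
#' @slot regressors timepoints x k numeric matrix.
#' @slot names character vector naming the k regressors.
#' @exportClass NuisanceSet
setClass("NuisanceSet",
  representation(regressors = "matrix", names = "character"))

setValidity("NuisanceSet", function(object) {
  msg <- character()
  if (!.isFiniteNumericMatrix(object@regressors))
    msg <- c(msg, "'regressors' must be a numeric matrix with finite entries")
  else if (ncol(object@regressors) < 1)
    msg <- c(msg, "a NuisanceSet needs at least one regressor")
  if (length(object@names) != ncol(object@regressors))
    msg <- c(msg, "'names' must name every regressor column")
  if (length(msg)) msg else TRUE
})

#' Construct a NuisanceSet
#'
#' @param regressors timepoints x k numeric matrix of confound signals.
#' @param names regressor names; defaults to the column names.
#' @return A [NuisanceSet-class] object.
#' @export
NuisanceSet <- function(regressors, names = colnames(regressors)) {
  regressors <- as.matrix(regressors)
  if (ncol(regressors) < 1)
    stop("a NuisanceSet needs at least one regressor")
  if (is.null(names))
    names <- paste0("nuisance", seq_len(ncol(regressors)))
  colnames(regressors) <- names
  new("NuisanceSet", regressors = regressors, names = as.character(names))
}

#' Integer ROI label map
#'
#' A 3-D integer array in which voxel value k > 0 assigns the voxel to ROI
#' k and 0 marks background, plus the names of the labelled ROIs.
#'
#' @slot grid 3-D integer array.
#' @slot labelNames character vector named by the integer labels (as
#'   character); label 0 is reserved for background and never named.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(grid = "array", labelNames = "character"))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3)
    msg <- c(msg, "'grid' must be a 3-D array")
  vals <- unique(as.vector(object@grid))
  vals <- vals[vals != 0]
  if (any(vals != as.integer(vals)))
    msg <- c(msg, "'grid' must contain integer labels")
  if (is.null(names(object@labelNames)))
    msg <- c(msg, "'labelNames' must be named by integer label")
  else if (!all(as.character(vals) %in% names(object@labelNames)))
    msg <- c(msg, "every nonzero label in 'grid' must appear in 'labelNames'")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMap
#'
#' @param grid 3-D integer array (0 = background).
#' @param labelNames character vector of ROI names, named by the integer
#'   labels used in `grid`.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(grid, labelNames) {
  new("LabelMap", grid = grid, labelNames = labelNames)
}

#' Weighted functional connectivity matrix
#'
#' Symmetric node x node Pearson correlations `r` together with the edge
#' weights `|atanh(r)|` (absolute Fisher r-to-z). Diagonals are stored as 0
#' and excluded from every edge enumeration, so a 24-node network has
#' 24*23/2 = 276 unique edges.
#'
#' @slot r symmetric correlation matrix, diagonal 0.
#' @slot weight symmetric nonnegative weight matrix, `abs(atanh(r))`
#'   off-diagonal, diagonal 0.
#' @slot nodeLabels node names.
#' @seealso [computeConnectivity()], [degreeCentrality()], [flattenEdges()].
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(r = "matrix", weight = "matrix", nodeLabels = "character"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  n <- length(object@nodeLabels)
  for (nm in c("r", "weight")) {
    m <- slot(object, nm)
    if (!.isFiniteNumericMatrix(m) || nrow(m) != n || ncol(m) != n)
      msg <- c(msg, sprintf("'%s' must be a finite %d x %d matrix", nm, n, n))
    else {
      if (max(abs(m - t(m))) > 1e-8)
        msg <- c(msg, sprintf("'%s' must be symmetric", nm))
      if (any(diag(m) != 0))
        msg <- c(msg, sprintf("diagonal of '%s' must be 0", nm))
    }
  }
  if (!length(msg)) {
    off <- upper.tri(object@r)
    if (any(abs(object@r[off]) >= 1))
      msg <- c(msg, "off-diagonal correlations must lie strictly in (-1, 1)")
    else if (max(abs(object@weight[off] - abs(atanh(object@r[off])))) > 1e-8)
      msg <- c(msg, "'weight' must equal abs(atanh(r)) off-diagonal")
    if (any(object@weight < 0))
      msg <- c(msg, "weights must be nonnegative")
  }
  if (anyDuplicated(object@nodeLabels))
    msg <- c(msg, "'nodeLabels' must be distinct")
  if (length(msg)) msg else TRUE
})

.ConnectivityMatrix <- function(r, nodeLabels) {
  w <- abs(atanh(r))
  diag(r) <- 0
  diag(w) <- 0
  dimnames(r) <- dimnames(w) <- list(nodeLabels, nodeLabels)
  new("ConnectivityMatrix", r = r, weight = w,
      nodeLabels = as.character(nodeLabels))
}

#' Result of one covariate-adjusted association test
#'
#' Holds the partial correlation between a behavioral measure and one
#' network quantity (a node's degree centrality or an edge weight) after
#' removing the linear effect of the covariates, together with its t
#' statistic, degrees of freedom (n - 2 - k for k covariates) and two-tailed
#' p-value.
#'
#' @slot rPartial partial correlation coefficient in (-1, 1).
#' @slot tStat t statistic `r * sqrt(df / (1 - r^2))`.
#' @slot df residual degrees of freedom, n - 2 - k.
#' @slot pTwoTailed two-tailed p-value from the t distribution.
#' @slot covariateNames names of the covariates controlled for.
#' @slot targetLabel node or edge identifier the test refers to.
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(
    rPartial = "numeric", tStat = "numeric", df = "numeric",
    pTwoTailed = "numeric", covariateNames = "character",
    targetLabel = "character"
  ),
  prototype(covariateNames = character(), targetLabel = NA_character_)
)

setValidity("AssociationResult", function(object) {
  msg <- character()
  if (abs(object@rPartial) > 1)
    msg <- c(msg, "'rPartial' must lie in [-1, 1]")
  if (object@df < 0) msg <- c(msg, "'df' must be nonnegative")
  if (object@pTwoTailed < 0 || object@pTwoTailed > 1)
    msg <- c(msg, "'pTwoTailed' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' All parameters of a synthetic study cohort: acquisition geometry
#' (183 volumes at TR = 2 s over 24 nodes by default), the target inter-node
#' correlation structure, temporal autocorrelation, the planted couplings
#' between connectivity and the masticatory performance index (MPI), the
#' behavioral noise level, the age structure of the two age groups and the
#' within-older-group age slope of the MPI, motion random-walk step sizes,
#' and the random seed.
#'
#' @slot nSubjects number of subjects.
#' @slot nTimepoints volumes per subject (default 183).
#' @slot samplingInterval TR in seconds (default 2).
#' @slot nodeLabels node names (default the 24 mastication ROIs).
#' @slot covarianceDesign target node x node correlation matrix (symmetric,
#'   unit diagonal, positive semidefinite).
#' @slot arCoefficient lag-1 autocorrelation of each node signal, in [0, 1).
#' @slot couplingPlan list of `list(target=, coefficient=)` entries; a
#'   target is a node label (couples MPI to its degree centrality) or
#'   `"A|B"` (couples MPI to the weight of edge A-B).
#' @slot behaviorNoiseSd SD of the Gaussian noise added to the MPI.
#' @slot mpiIntercept baseline MPI (Delta-E units).
#' @slot ageRangeYounger,ageRangeOlder (min, max) age in years per group.
#' @slot ageMpiSlopeOlder MPI change per year of age beyond the group
#'   boundary, applied within the older group only (negative = decline).
#' @slot maleProportion probability a subject is male.
#' @slot stepSdMm,stepSdDeg per-frame motion random-walk step SDs.
#' @slot seed integer random seed.
#' @seealso [CohortSpec()], [generateCohort()].
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nSubjects = "numeric", nTimepoints = "numeric",
    samplingInterval = "numeric", nodeLabels = "character",
    covarianceDesign = "matrix", arCoefficient = "numeric",
    couplingPlan = "list", behaviorNoiseSd = "numeric",
    mpiIntercept = "numeric", ageRangeYounger = "numeric",
    ageRangeOlder = "numeric", ageMpiSlopeOlder = "numeric",
    maleProportion = "numeric", stepSdMm = "numeric", stepSdDeg = "numeric",
    seed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1) msg <- c(msg, "'nSubjects' must be positive")
  if (object@nTimepoints < 10)
    msg <- c(msg, "'nTimepoints' must be at least 10")
  if (object@samplingInterval <= 0)
    msg <- c(msg, "'samplingInterval' must be positive")
  n <- length(object@nodeLabels)
  if (anyDuplicated(object@nodeLabels))
    msg <- c(msg, "'nodeLabels' must be distinct")
  S <- object@covarianceDesign
  if (!.isFiniteNumericMatrix(S) || nrow(S) != n || ncol(S) != n)
    msg <- c(msg, sprintf("'covarianceDesign' must be a finite %d x %d matrix", n, n))
  else {
    if (max(abs(S - t(S))) > 1e-10)
      msg <- c(msg, "'covarianceDesign' must be symmetric")
    if (max(abs(diag(S) - 1)) > 1e-10)
      msg <- c(msg, "'covarianceDesign' must have unit diagonal")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      msg <- c(msg, sprintf(
        "'covarianceDesign' is not positive semidefinite (smallest eigenvalue %.3e)",
        min(ev)))
  }
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    msg <- c(msg, "'arCoefficient' must lie in [0, 1)")
  if (object@behaviorNoiseSd < 0)
    msg <- c(msg, "'behaviorNoiseSd' must be nonnegative")
  for (cp in object@couplingPlan) {
    if (!is.list(cp) || is.null(cp$target) || is.null(cp$coefficient))
      msg <- c(msg, "each couplingPlan entry needs 'target' and 'coefficient'")
  }
  if (length(msg)) msg else TRUE
})
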