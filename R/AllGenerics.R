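#' Node labels of a network object
#'
#' @param x an [ROITimeSeries-class], [ConnectivityMatrix-class] or
#'   [CohortSpec-class] object.
#' @return Character vector of node names.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "ROITimeSeries", function(x) x@nodeLabels)

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "ConnectivityMatrix", function(x) x@nodeLabels)

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "CohortSpec", function(x) x@nodeLabels)

#' Number of timepoints
#'
#' @param x an [ROITimeSeries-class] or [MotionTrace-class] object.
#' @return Integer number of rows (volumes).
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "ROITimeSeries", function(x) nrow(x@data))

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "MotionTrace", function(x) nrow(x@data))

#' Sampling interval (TR) in seconds
#'
#' @param x an [ROITimeSeries-class] object.
#' @return Positive scalar.
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @rdname samplingInterval
#' @export
setMethod("samplingInterval", "ROITimeSeries", function(x) x@samplingInterval)

#' Underlying numeric matrix of a time-series-like object
#'
#' @param x an [ROITimeSeries-class] or [MotionTrace-class] object.
#' @return The timepoints x variables matrix.
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @rdname seriesData
#' @export
setMethod("seriesData", "ROITimeSeries", function(x) x@data)

#' @rdname seriesData
#' @export
setMethod("seriesData", "MotionTrace", function(x) x@data)

#' Preprocessing stages applied to a series
#'
#' @param x an [ROITimeSeries-class] object.
#' @return Character vector of stage names, in order of application.
#' @export
setGeneric("processingSteps", function(x) standardGeneric("processingSteps"))

#' @rdname processingSteps
#' @export
setMethod("processingSteps", "ROITimeSeries", function(x) x@steps)

#' Correlation and weight matrices of a connectivity object
#'
#' `connectivityR` returns the Pearson correlation matrix (diagonal 0);
#' `edgeWeights` returns the absolute Fisher-z weight matrix.
#'
#' @param x a [ConnectivityMatrix-class] object.
#' @return A symmetric numeric matrix with node labels as dimnames.
#' @export
setGeneric("connectivityR", function(x) standardGeneric("connectivityR"))

#' @rdname connectivityR
#' @export
setMethod("connectivityR", "ConnectivityMatrix", function(x) x@r)

#' @rdname connectivityR
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname connectivityR
#' @export
setMethod("edgeWeights", "ConnectivityMatrix", function(x) x@weight)

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf("ROITimeSeries: %d timepoints x %d nodes (TR = %g s)\n",
              nrow(object@data), ncol(object@data), object@samplingInterval))
  cat(" nodes:", paste(utils::head(object@nodeLabels, 6), collapse = ", "),
      if (length(object@nodeLabels) > 6) "..." else "", "\n")
  cat(" steps applied:",
      if (length(object@steps)) paste(object@steps, collapse = " -> ")
      else "(none)", "\n")
})

setMethod("show", "MotionTrace", function(object) {
  md <- meanDisplacement(object)
  cat(sprintf(
    "MotionTrace: %d timepoints; mean displacement %.4f mm / %.4f deg\n",
    nrow(object@data), md[["mean_translation_mm"]],
    md[["mean_rotation_deg"]]))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- length(object@nodeLabels)
  cat(sprintf(
    "ConnectivityMatrix: %d nodes, %d unique edges; mean |z| weight %.3f\n",
    n, n * (n - 1) / 2, mean(object@weight[upper.tri(object@weight)])))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf(
    "AssociationResult [%s]: r_partial = %.3f, t(%d) = %.3f, p = %.4g\n",
    object@targetLabel, object@rPartial, object@df, object@tStat,
    object@pTwoTailed))
  if (length(object@covariateNames))
    cat(" controlling for:", paste(object@covariateNames, collapse = ", "),
        "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subjects, %d volumes @ TR %g s, %d nodes, seed %d\n",
    object@nSubjects, object@nTimepoints, object@samplingInterval,
    length(object@nodeLabels), object@seed))
  cat(sprintf(" AR(1) = %g, behavior noise SD = %g, %d planted coupling(s)\n",
              object@arCoefficient, object@behaviorNoiseSd,
              length(object@couplingPlan)))
})
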