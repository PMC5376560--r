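#' Absolute Fisher r-to-z edge weight
#'
#' Converts a Pearson correlation to the network edge weight
#' `|atanh(r)| = |0.5 * log((1 + r) / (1 - r))|`: the Fisher
#' variance-stabilizing transform followed by the absolute value, so that
#' strong negative correlations carry the same weight as strong positive
#' ones. Correlations with `|r| >= 1` have infinite weight and are
#' rejected; `clip = TRUE` first clips r to `+/-(1 - 1e-7)`.
#'
#' @param r numeric vector of correlations.
#' @param clip logical; clip `|r|` at `1 - 1e-7` instead of erroring.
#' @return Nonnegative weights, same length as `r`.
#' @examples
#' fisherZWeight(c(0, 0.9, -0.5))
#' @export
fisherZWeight <- function(r, clip = FALSE) {
  if (any(!is.finite(r))) stop("'r' must be finite")
  if (clip) {
    lim <- 1 - 1e-7
    r <- pmin(pmax(r, -lim), lim)
  } else if (any(abs(r) >= 1)) {
    stop("|r| >= 1 gives an infinite Fisher z weight; enable 'clip' to proceed")
  }
  abs(atanh(r))
}

#' Build the weighted connectivity matrix of one subject
#'
#' Pearson correlation between every pair of regional mean time series,
#' converted to edge weights by the absolute Fisher r-to-z transform. For
#' 24 nodes this yields the undirected weighted network of 276 unique
#' edges.
#'
#' @param series an [ROITimeSeries-class] with at least 3 timepoints; every
#'   node must have nonzero variance.
#' @param clip logical; clip perfect correlations between distinct nodes at
#'   `1 - 1e-7` instead of erroring.
#' @return A [ConnectivityMatrix-class].
#' @examples
#' ts <- generateSubjectTimeSeries(diag(3), 50, 0, 2, 1, c("A", "B", "C"))
#' computeConnectivity(ts)
#' @export
computeConnectivity <- function(series, clip = FALSE) {
  stopifnot(is(series, "ROITimeSeries"))
  X <- series@data
  if (nrow(X) < 3) stop("connectivity needs at least 3 timepoints")
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop(sprintf("node '%s' has zero variance; its correlations are undefined",
                 series@nodeLabels[which(v == 0)[1]]))
  R <- stats::cor(X)
  off <- abs(R[upper.tri(R)])
  if (any(off >= 1)) {
    if (!clip)
      stop("a pair of distinct nodes is perfectly correlated (|r| = 1); enable 'clip' to proceed")
    lim <- 1 - 1e-7
    R <- pmin(pmax(R, -lim), lim)
  }
  .ConnectivityMatrix(R, series@nodeLabels)
}

#' Weighted degree centrality
#'
#' The degree centrality (DC) of node k is the sum of the weights of its
#' n - 1 incident edges; a high-DC node is a network hub. The DC values
#' sum to twice the total unique-edge weight.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @return Named numeric vector of per-node DC values.
#' @export
degreeCentrality <- function(cm) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  stats::setNames(rowSums(cm@weight), cm@nodeLabels)
}

#' Enumerate the unique edges of a network
#'
#' Deterministic listing of the n(n-1)/2 unique node pairs (i before j in
#' node-label order) with their correlation and weight.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @return data.frame with columns `node_i`, `node_j`, `r`, `weight`,
#'   ordered by (i, j).
#' @export
flattenEdges <- function(cm) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  n <- length(cm@nodeLabels)
  idx <- which(upper.tri(cm@r), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    node_i = cm@nodeLabels[idx[, 1]],
    node_j = cm@nodeLabels[idx[, 2]],
    r = cm@r[idx],
    weight = cm@weight[idx],
    stringsAsFactors = FALSE
  )
}

#' Edge identifier used across the package
#'
#' @param i,j node labels.
#' @return `"i|j"` character vector.
#' @export
edgeName <- function(i, j) paste(i, j, sep = "|")

#' Stack per-subject edge weights into a subject x edge matrix
#'
#' @param cmList named list of [ConnectivityMatrix-class] objects sharing
#'   the same node labels.
#' @return subjects x edges numeric matrix; columns named `"A|B"` in the
#'   order of [flattenEdges()].
#' @export
edgeWeightMatrix <- function(cmList) {
  stopifnot(length(cmList) >= 1)
  labels <- cmList[[1]]@nodeLabels
  edges <- flattenEdges(cmList[[1]])
  out <- t(vapply(cmList, function(cm) {
    if (!identical(cm@nodeLabels, labels))
      stop("all subjects must share the same node labels, in the same order")
    flattenEdges(cm)$weight
  }, numeric(nrow(edges))))
  colnames(out) <- edgeName(edges$node_i, edges$node_j)
  rownames(out) <- names(cmList)
  out
}

#' Stack per-subject degree centralities into a subject x node matrix
#'
#' @param cmList named list of [ConnectivityMatrix-class] objects sharing
#'   the same node labels.
#' @return subjects x nodes numeric matrix.
#' @export
dcMatrix <- function(cmList) {
  stopifnot(length(cmList) >= 1)
  labels <- cmList[[1]]@nodeLabels
  out <- t(vapply(cmList, function(cm) {
    if (!identical(cm@nodeLabels, labels))
      stop("all subjects must share the same node labels, in the same order")
    degreeCentrality(cm)
  }, numeric(length(labels))))
  colnames(out) <- labels
  rownames(out) <- names(cmList)
  out
}
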