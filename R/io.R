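# Plain-text readers/writers. Every writer-reader pair is an identity on
# the persisted object (numeric fields to full double precision via %.17g).

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read a phenotype table
#'
#' TSV with header `subject_id age gender group mpi`. Reading validates
#' completeness: a missing or non-numeric age/mpi cell is an error naming
#' the row.
#'
#' @param phenotypes data.frame with the five phenotype columns.
#' @param path file path.
#' @return `readPhenotypes` returns the validated data.frame.
#' @export
writePhenotypes <- function(phenotypes, path) {
  out <- phenotypes
  out$age <- .fmtNum(out$age)
  out$mpi <- .fmtNum(out$mpi)
  .writeTSV(out, path)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  needed <- c("subject_id", "age", "gender", "group", "mpi")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  for (col in c("age", "mpi")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad))
      stop(sprintf("%s: row %d (subject '%s') has a missing or invalid '%s'",
                   path, bad[1], df$subject_id[bad[1]], col))
    df[[col]] <- val
  }
  df
}

#' Write / read an ROI time series as TSV
#'
#' One row per timepoint, header = node labels; the sampling interval is
#' kept in a `#samplingIntervalS=` comment line so the round trip restores
#' the full object.
#'
#' @param series an [ROITimeSeries-class].
#' @param path file path.
#' @return `readTimeSeriesTSV` returns the [ROITimeSeries-class].
#' @export
writeTimeSeriesTSV <- function(series, path) {
  stopifnot(is(series, "ROITimeSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#samplingIntervalS=%s", .fmtNum(series@samplingInterval)),
             con)
  writeLines(paste(series@nodeLabels, collapse = "\t"), con)
  utils::write.table(
    matrix(.fmtNum(series@data), nrow(series@data)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeriesTSV
#' @param samplingInterval TR in seconds, used only when the file carries
#'   no `#samplingIntervalS=` line.
#' @export
readTimeSeriesTSV <- function(path, samplingInterval = NULL) {
  first <- readLines(path, n = 1)
  skip <- 0
  if (startsWith(first, "#samplingIntervalS=")) {
    samplingInterval <- as.numeric(sub("#samplingIntervalS=", "", first))
    skip <- 1
  }
  if (is.null(samplingInterval))
    stop(sprintf("%s: no sampling interval in file; pass 'samplingInterval'",
                 path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE)
  m <- as.matrix(df)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: non-finite value at timepoint %d, node '%s'",
                 path, bad[1, 1], colnames(m)[bad[1, 2]]))
  ROITimeSeries(m, nodeLabels = colnames(m),
                samplingInterval = samplingInterval)
}

#' Write / read a motion trace as TSV
#'
#' Header `tx ty tz rx ry rz` (mm, mm, mm, deg, deg, deg).
#'
#' @param trace a [MotionTrace-class].
#' @param path file path.
#' @return `readMotionTrace` returns the [MotionTrace-class].
#' @export
writeMotionTrace <- function(trace, path) {
  stopifnot(is(trace, "MotionTrace"))
  df <- as.data.frame(matrix(.fmtNum(trace@data), nrow(trace@data)))
  names(df) <- .motionColumns
  .writeTSV(df, path)
  invisible(path)
}

#' @rdname writeMotionTrace
#' @export
readMotionTrace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!identical(names(df), .motionColumns))
    stop(sprintf("%s: expected header '%s'", path,
                 paste(.motionColumns, collapse = " ")))
  m <- as.matrix(df)
  if (any(!is.finite(m)))
    stop(sprintf("%s: non-finite motion value at row %d", path,
                 which(rowSums(!is.finite(m)) > 0)[1]))
  MotionTrace(m)
}

#' Write / read a connectivity matrix as TSV
#'
#' The correlation matrix is persisted as a labelled TSV (header row and
#' leading label column); the weight matrix is reconstructed on read from
#' the invariant `weight = |atanh(r)|`. `writeWeightMatrixTSV` exports the
#' weight variant for display.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path file path.
#' @return `readConnectivityMatrix` returns the
#'   [ConnectivityMatrix-class].
#' @export
writeConnectivityMatrix <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  .writeLabelledMatrix(cm@r, cm@nodeLabels, path)
}

#' @rdname writeConnectivityMatrix
#' @export
writeWeightMatrixTSV <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  .writeLabelledMatrix(cm@weight, cm@nodeLabels, path)
}

.writeLabelledMatrix <- function(m, labels, path) {
  df <- data.frame(node = labels, matrix(.fmtNum(m), nrow(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("node", labels)
  .writeTSV(df, path)
  invisible(path)
}

#' @rdname writeConnectivityMatrix
#' @export
readConnectivityMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), as.character(labels)))
    stop(sprintf("%s: row and column labels disagree", path))
  if (any(!is.finite(m)))
    stop(sprintf("%s: non-finite matrix entry", path))
  rownames(m) <- labels
  .ConnectivityMatrix(m, as.character(labels))
}

#' Write the edge list of a network
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeEdgeList <- function(cm, path) {
  edges <- flattenEdges(cm)
  edges$r <- .fmtNum(edges$r)
  edges$weight <- .fmtNum(edges$weight)
  .writeTSV(edges, path)
  invisible(path)
}

#' Write / read a volume or label map as NIfTI-1
#'
#' Volumes are stored as floating point; label maps as integers with their
#' label names in a JSON sidecar (`<path>.labels.json`) so the round trip
#' restores the [LabelMap-class] exactly.
#'
#' @param volume numeric array (3-D or 4-D).
#' @param labelMap a [LabelMap-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return Readers return the array / [LabelMap-class].
#' @export
writeVolumeNIfTI <- function(volume, path) {
  RNifti::writeNifti(volume, path)
  invisible(path)
}

#' @rdname writeVolumeNIfTI
#' @export
readVolumeNIfTI <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' @rdname writeVolumeNIfTI
#' @export
writeLabelMapNIfTI <- function(labelMap, path) {
  stopifnot(is(labelMap, "LabelMap"))
  img <- array(as.integer(labelMap@grid), dim(labelMap@grid))
  RNifti::writeNifti(img, path, datatype = "int32")
  jsonlite::write_json(as.list(labelMap@labelNames),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeVolumeNIfTI
#' @export
readLabelMapNIfTI <- function(path) {
  arr <- RNifti::readNifti(path)
  names <- jsonlite::read_json(paste0(path, ".labels.json"),
                               simplifyVector = TRUE)
  d <- dim(arr)
  if (length(d) < 3) d <- c(d, rep(1L, 3 - length(d)))  # dropped singletons
  LabelMap(array(as.integer(arr), d), unlist(names))
}

#' Write / read a ground-truth record as JSON
#'
#' @param groundTruth the `groundTruth` element of [generateCohort()]'s
#'   return value.
#' @param path file path.
#' @return `readGroundTruthJSON` returns the parsed list.
#' @export
writeGroundTruthJSON <- function(groundTruth, path) {
  gt <- groundTruth
  gt$realized <- if (length(gt$realized)) as.data.frame(gt$realized) else NULL
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruthJSON
#' @export
readGroundTruthJSON <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
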