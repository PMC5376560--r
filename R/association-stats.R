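#' Partial correlation with t-based inference
#'
#' Correlation between `x` and `y` after removing the linear effect of the
#' covariates from both: each variable is regressed (OLS, with intercept)
#' on the covariates and the Pearson correlation of the two residual
#' vectors is taken. Inference uses `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k` for k covariates and a two-tailed p from the t
#' distribution. With no covariates this reduces exactly to the ordinary
#' Pearson correlation with `df = n - 2`.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates numeric matrix (n x k) or NULL for none.
#' @param covariateNames names recorded in the result; defaults to the
#'   matrix column names.
#' @param targetLabel identifier stored in the result (for tables).
#' @return An [AssociationResult-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(40); z <- rnorm(40); y <- 0.5 * x + 0.8 * z + rnorm(40)
#' partialCorrelation(x, y, cbind(z = z))
#' @export
partialCorrelation <- function(x, y, covariates = NULL,
                               covariateNames = colnames(covariates),
                               targetLabel = NA_character_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("'covariates' must have one row per subject")
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < k + 4)
    stop(sprintf("need at least %d subjects for %d covariate(s), got %d",
                 k + 4, k, n))
  if (is.null(covariateNames) && k > 0)
    covariateNames <- paste0("covariate", seq_len(k))
  X <- cbind(intercept = rep(1, n), covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("covariate matrix (with intercept) is rank deficient")
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  # residuals of a constant (or fully explained) variable are zero up to
  # rounding; compare to the variable's own scale
  degenerate <- function(res, orig)
    stats::sd(res) <= 1e-10 * max(1, mean(abs(orig)))
  if (degenerate(rx, x) || degenerate(ry, y))
    stop("zero residual variance: the variable is constant or fully explained by the covariates")
  r <- stats::cor(rx, ry)
  if (abs(r) >= 1)
    stop("|partial correlation| = 1: degenerate input")
  df <- n - 2L - k
  tStat <- r * sqrt(df / (1 - r^2))
  new("AssociationResult",
      rPartial = r, tStat = tStat, df = as.numeric(df),
      pTwoTailed = 2 * stats::pt(-abs(tStat), df),
      covariateNames = as.character(covariateNames %||% character()),
      targetLabel = as.character(targetLabel))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkPhenotypes <- function(phenotypes) {
  needed <- c("subject_id", "age", "gender", "mpi")
  missing <- setdiff(needed, names(phenotypes))
  if (length(missing))
    stop("phenotype table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("age", "gender", "mpi")) {
    bad <- is.na(phenotypes[[col]]) |
      (col != "gender" & !is.finite(suppressWarnings(as.numeric(phenotypes[[col]]))))
    if (any(bad))
      stop(sprintf("subject '%s' has a missing or non-finite '%s'",
                   phenotypes$subject_id[which(bad)[1]], col))
  }
  if (!all(phenotypes$gender %in% c("M", "F")))
    stop("'gender' must be coded M or F")
  invisible(TRUE)
}

.covariateMatrix <- function(phenotypes) {
  cbind(age = as.numeric(phenotypes$age),
        gender = as.numeric(phenotypes$gender == "M"))
}

.resultRow <- function(res, flagName, flag) {
  out <- data.frame(
    label = res@targetLabel, r_partial = res@rPartial, t = res@tStat,
    df = res@df, p = res@pTwoTailed, stringsAsFactors = FALSE)
  out[[flagName]] <- flag
  out
}

#' Identify mastication-related hubs
#'
#' For every node, the partial correlation between its degree centrality
#' and the MPI is computed across subjects, controlling for age and gender
#' (coded F = 0, M = 1). A node is flagged as a hub when the partial
#' correlation is positive and its two-tailed p falls below `alpha`. All
#' nodes are reported whether or not they qualify; no multiple-testing
#' adjustment is applied.
#'
#' @param dcBySubject subjects x nodes matrix of degree centralities (see
#'   [dcMatrix()]); rows must align with `phenotypes`.
#' @param phenotypes data.frame with columns subject_id, age, gender, mpi.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `label, r_partial, t, df, p, is_hub`,
#'   one row per node.
#' @export
identifyHubs <- function(dcBySubject, phenotypes, alpha = 0.05) {
  .checkPhenotypes(phenotypes)
  dcBySubject <- as.matrix(dcBySubject)
  if (nrow(dcBySubject) != nrow(phenotypes))
    stop("'dcBySubject' and 'phenotypes' must cover the same subjects")
  if (nrow(phenotypes) < 8)
    stop("hub identification needs at least 8 subjects")
  Z <- .covariateMatrix(phenotypes)
  mpi <- as.numeric(phenotypes$mpi)
  rows <- lapply(colnames(dcBySubject), function(node) {
    res <- partialCorrelation(dcBySubject[, node], mpi, Z,
                              covariateNames = c("age", "gender"),
                              targetLabel = node)
    .resultRow(res, "is_hub", res@rPartial > 0 && res@pTwoTailed < alpha)
  })
  do.call(rbind, rows)
}

#' Screen edges for association with behavior
#'
#' For every unique edge, the partial correlation between its weight and
#' the MPI is computed across subjects, controlling for age and gender.
#' The signed partial correlation is reported; an edge is flagged
#' significant when its two-tailed p falls below `alpha`, deliberately
#' without multiple-testing adjustment (exploratory screening).
#'
#' @param weightsBySubject subjects x edges matrix (see
#'   [edgeWeightMatrix()]); columns named `"A|B"`.
#' @param phenotypes data.frame with columns subject_id, age, gender, mpi.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns
#'   `node_i, node_j, label, r_partial, t, df, p, significant`, one row per
#'   edge (276 for 24 nodes).
#' @export
screenEdges <- function(weightsBySubject, phenotypes, alpha = 0.05) {
  .checkPhenotypes(phenotypes)
  weightsBySubject <- as.matrix(weightsBySubject)
  if (nrow(weightsBySubject) != nrow(phenotypes))
    stop("'weightsBySubject' and 'phenotypes' must cover the same subjects")
  if (nrow(phenotypes) < 8)
    stop("edge screening needs at least 8 subjects")
  Z <- .covariateMatrix(phenotypes)
  mpi <- as.numeric(phenotypes$mpi)
  rows <- lapply(colnames(weightsBySubject), function(edge) {
    res <- partialCorrelation(weightsBySubject[, edge], mpi, Z,
                              covariateNames = c("age", "gender"),
                              targetLabel = edge)
    .resultRow(res, "significant", res@pTwoTailed < alpha)
  })
  tab <- do.call(rbind, rows)
  nodes <- do.call(rbind, strsplit(tab$label, "|", fixed = TRUE))
  cbind(data.frame(node_i = nodes[, 1], node_j = nodes[, 2],
                   stringsAsFactors = FALSE), tab)
}

#' Median split of a cohort by age
#'
#' Splits subjects at the median age: strictly above the threshold is
#' "older", strictly below is "younger". A subject whose age equals the
#' threshold cannot be assigned and raises an error naming the tied
#' subjects (ties are never broken silently).
#'
#' @param phenotypes data.frame with columns subject_id and age.
#' @return List with `threshold_age` and `assignment`, a character vector
#'   of "older"/"younger" named by subject id.
#' @examples
#' ph <- data.frame(subject_id = c("a", "b", "c", "d"), age = c(1, 2, 3, 4))
#' medianSplit(ph)
#' @export
medianSplit <- function(phenotypes) {
  age <- as.numeric(phenotypes$age)
  if (length(age) < 2) stop("median split needs at least 2 subjects")
  threshold <- stats::median(age)
  tied <- age == threshold
  if (any(tied))
    stop("age ties at the median split threshold (", threshold, "): ",
         paste(phenotypes$subject_id[tied], collapse = ", "))
  list(
    threshold_age = threshold,
    assignment = stats::setNames(ifelse(age > threshold, "older", "younger"),
                                 phenotypes$subject_id)
  )
}

.summaryT <- function(m1, s1, n1, m2, s2, n2, mode) {
  if (mode == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    tStat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    tStat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  list(t = tStat, df = df, p_two_tailed = 2 * stats::pt(-abs(tStat), df))
}

#' Two-tailed two-sample t test
#'
#' Welch (default) or pooled-variance Student statistic, from raw data or
#' from per-group summary statistics (mean, sd, n); both routes use the
#' identical formulae.
#'
#' @param groupA,groupB numeric vectors of raw observations (ignored when
#'   summaries are supplied).
#' @param mode `"welch"` or `"pooled"`.
#' @param summaryA,summaryB optional `c(mean, sd, n)` per group.
#' @return List with `t`, `df`, `p_two_tailed`.
#' @examples
#' twoSampleT(summaryA = c(70.5, 3.3, 26), summaryB = c(73.3, 1.6, 26))
#' @export
twoSampleT <- function(groupA = NULL, groupB = NULL,
                       mode = c("welch", "pooled"),
                       summaryA = NULL, summaryB = NULL) {
  mode <- match.arg(mode)
  if (!is.null(summaryA) || !is.null(summaryB)) {
    if (is.null(summaryA) || is.null(summaryB))
      stop("supply summaries for both groups or neither")
    if (summaryA[2] <= 0 || summaryB[2] <= 0)
      stop("summary standard deviations must be positive")
    if (summaryA[3] < 2 || summaryB[3] < 2)
      stop("each group needs n >= 2")
    return(.summaryT(summaryA[1], summaryA[2], summaryA[3],
                     summaryB[1], summaryB[2], summaryB[3], mode))
  }
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(groupA, groupB, var.equal = (mode == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_tailed = ht$p.value)
}

#' Chi-square test on a 2 x 2 contingency table
#'
#' Pearson chi-square with 1 degree of freedom; by default the Yates
#' continuity correction is applied with the `|O - E| - 0.5` term clamped
#' at zero (so a perfectly balanced table yields exactly 0).
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts; all row and
#'   column totals must be positive.
#' @param continuityCorrection logical, default TRUE.
#' @return List with `chi2`, `df` (= 1) and `p_two_tailed`.
#' @examples
#' chiSquare2x2(matrix(c(7, 12, 19, 14), 2))  # chi2 = 1.33, p = 0.25
#' @export
chiSquare2x2 <- function(counts, continuityCorrection = TRUE) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)))
    stop("'counts' must be a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("every row and column total must be positive")
  ht <- suppressWarnings(
    stats::chisq.test(counts, correct = continuityCorrection))
  list(chi2 = unname(ht$statistic), df = 1L, p_two_tailed = ht$p.value)
}

#' Pearson correlation with two-tailed p
#'
#' Standard product-moment correlation; the p-value comes from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with positive
#'   variance.
#' @return List with `r`, `df` and `p_two_tailed`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y)
  list(r = unname(ht$estimate), df = unname(ht$parameter),
       p_two_tailed = ht$p.value)
}
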