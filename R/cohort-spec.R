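#' The 24 mastication-network node labels
#'
#' Twelve bilateral regions implicated in motor control or mastication,
#' left hemisphere before right within each region: primary motor cortex
#' (M1), premotor cortex (PMC), primary and secondary somatosensory
#' cortices (S1, S2), superior parietal lobe (SPL), anterior insula (aINS),
#' dorsal anterior cingulate cortex (dACC), caudate nucleus (CaN), thalamus
#' (THA), and three cerebellar subdivisions (CAnt, CPost67, CPost8).
#'
#' @return Character vector of length 24, e.g. `"M1_L"`, `"M1_R"`, ...
#' @examples
#' masticationNodeLabels()
#' @export
masticationNodeLabels <- function() {
  regions <- c("M1", "PMC", "S1", "S2", "SPL", "aINS", "dACC",
               "CaN", "THA", "CAnt", "CPost67", "CPost8")
  as.vector(t(outer(regions, c("_L", "_R"), paste0)))
}

#' Default target correlation structure for synthetic cohorts
#'
#' A positive-definite 24 x 24 correlation matrix with a qualitative block
#' structure resembling a sensorimotor system: a sensorimotor block (M1,
#' PMC, S1, S2), a cerebellar block (CAnt, CPost67, CPost8), a subcortical
#' block (CaN, THA), moderate cortico-cerebellar and subcortico-cerebellar
#' cross-links, strong homotopic (left-right) pairs, and a weak baseline
#' everywhere else. The numeric values are free simulation parameters, not
#' empirical estimates.
#'
#' @param nodeLabels node labels; must follow the `"<region>_<L/R>"` naming
#'   of [masticationNodeLabels()].
#' @return A symmetric unit-diagonal positive-definite matrix.
#' @examples
#' S <- defaultCovarianceDesign()
#' min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
defaultCovarianceDesign <- function(nodeLabels = masticationNodeLabels()) {
  reg <- sub("_[LR]$", "", nodeLabels)
  n <- length(nodeLabels)
  R <- matrix(0.05, n, n)
  blocks <- list(
    sensorimotor = c("M1", "PMC", "S1", "S2"),
    cerebellum = c("CAnt", "CPost67", "CPost8"),
    subcortical = c("CaN", "THA")
  )
  within <- c(sensorimotor = 0.40, cerebellum = 0.40, subcortical = 0.35)
  for (b in names(blocks)) {
    idx <- reg %in% blocks[[b]]
    R[idx, idx] <- within[[b]]
  }
  setCross <- function(R, a, b, v) {
    ia <- reg %in% blocks[[a]]
    ib <- reg %in% blocks[[b]]
    R[ia, ib] <- v
    R[ib, ia] <- v
    R
  }
  R <- setCross(R, "sensorimotor", "cerebellum", 0.20)
  R <- setCross(R, "subcortical", "cerebellum", 0.20)
  R <- setCross(R, "sensorimotor", "subcortical", 0.15)
  # homotopic pairs sit adjacently (L then R)
  for (i in seq(1, n - 1, by = 2)) {
    if (reg[i] == reg[i + 1]) R[i, i + 1] <- R[i + 1, i] <- 0.60
  }
  diag(R) <- 1
  dimnames(R) <- list(nodeLabels, nodeLabels)
  R
}

#' Specify a synthetic cohort
#'
#' Builds a validated [CohortSpec-class]. Defaults emulate the study
#' conditions: 183 volumes at TR = 2 s over the 24 mastication nodes, a
#' median-split age structure (younger 23-54 y, older 55-74 y), an MPI
#' baseline of 73.3 Delta-E units with an age-related decline of -0.25
#' units/year within the older group, behavioral noise SD 1.5, lag-1
#' autocorrelation 0.4, and small motion random walks that keep every
#' subject below the 1.5 mm / 1.5 degree exclusion limits.
#'
#' @param nSubjects number of subjects.
#' @param nTimepoints volumes per subject.
#' @param samplingInterval TR in seconds.
#' @param nodeLabels node names.
#' @param covarianceDesign target correlation matrix (symmetric, unit
#'   diagonal, PSD); rejected otherwise with the offending eigenvalue.
#' @param arCoefficient lag-1 autocorrelation, in [0, 1).
#' @param couplingPlan list of `list(target, coefficient)`; see
#'   [CohortSpec-class].
#' @param behaviorNoiseSd MPI noise SD (Delta-E units).
#' @param mpiIntercept baseline MPI.
#' @param ageRangeYounger,ageRangeOlder (min, max) ages per group.
#' @param ageMpiSlopeOlder MPI units per year within the older group.
#' @param maleProportion probability of male gender.
#' @param stepSdMm,stepSdDeg motion random-walk step SDs.
#' @param seed integer seed.
#' @return A validated [CohortSpec-class].
#' @examples
#' spec <- CohortSpec(nSubjects = 10, seed = 1)
#' spec
#' @export
CohortSpec <- function(nSubjects,
                       nTimepoints = 183,
                       samplingInterval = 2,
                       nodeLabels = masticationNodeLabels(),
                       covarianceDesign = defaultCovarianceDesign(nodeLabels),
                       arCoefficient = 0.4,
                       couplingPlan = list(),
                       behaviorNoiseSd = 1.5,
                       mpiIntercept = 73.3,
                       ageRangeYounger = c(23, 54),
                       ageRangeOlder = c(55, 74),
                       ageMpiSlopeOlder = -0.25,
                       maleProportion = 19 / 52,
                       stepSdMm = 0.02,
                       stepSdDeg = 0.02,
                       seed = 7) {
  new("CohortSpec",
      nSubjects = as.numeric(nSubjects),
      nTimepoints = as.numeric(nTimepoints),
      samplingInterval = as.numeric(samplingInterval),
      nodeLabels = as.character(nodeLabels),
      covarianceDesign = covarianceDesign,
      arCoefficient = as.numeric(arCoefficient),
      couplingPlan = couplingPlan,
      behaviorNoiseSd = as.numeric(behaviorNoiseSd),
      mpiIntercept = as.numeric(mpiIntercept),
      ageRangeYounger = as.numeric(ageRangeYounger),
      ageRangeOlder = as.numeric(ageRangeOlder),
      ageMpiSlopeOlder = as.numeric(ageMpiSlopeOlder),
      maleProportion = as.numeric(maleProportion),
      stepSdMm = as.numeric(stepSdMm),
      stepSdDeg = as.numeric(stepSdDeg),
      seed = as.numeric(seed))
}
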