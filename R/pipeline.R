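#' Assemble a pipeline configuration
#'
#' Exactly one of `cohort` (a [CohortSpec-class]; the cohort is simulated)
#' or `paths` (a list with `phenotypes`, `seriesDir`, `motionDir`; the
#' cohort is read from disk) must be supplied.
#'
#' @param cohort a [CohortSpec-class], or NULL.
#' @param paths list of input paths, or NULL. Series and motion files are
#'   expected as `<seriesDir>/<subject_id>.tsv` and
#'   `<motionDir>/<subject_id>.tsv`.
#' @param nDiscard initial volumes to drop (default 3).
#' @param lowHz,highHz bandpass edges in Hz (defaults 0.01 and 0.08).
#' @param filterNuisance bandpass the nuisance regressors before
#'   regression (default FALSE).
#' @param alpha significance level for hub and edge tables.
#' @param tMode `"welch"` or `"pooled"` for group comparisons.
#' @param transLimit,rotLimit motion exclusion limits (mm, degrees).
#' @param outDir output directory, or NULL to keep everything in memory.
#' @return A validated config list for [runPipeline()].
#' @export
pipelineConfig <- function(cohort = NULL, paths = NULL, nDiscard = 3,
                           lowHz = 0.01, highHz = 0.08,
                           filterNuisance = FALSE, alpha = 0.05,
                           tMode = c("welch", "pooled"), transLimit = 1.5,
                           rotLimit = 1.5, outDir = NULL) {
  if (is.null(cohort) == is.null(paths))
    stop("supply exactly one of 'cohort' (synthetic) or 'paths' (files)")
  if (!is.null(cohort)) stopifnot(is(cohort, "CohortSpec"))
  if (!is.null(paths)) {
    needed <- c("phenotypes", "seriesDir", "motionDir")
    if (!all(needed %in% names(paths)))
      stop("'paths' needs elements: ", paste(needed, collapse = ", "))
  }
  list(cohort = cohort, paths = paths, nDiscard = nDiscard, lowHz = lowHz,
       highHz = highHz, filterNuisance = filterNuisance, alpha = alpha,
       tMode = match.arg(tMode), transLimit = transLimit,
       rotLimit = rotLimit, outDir = outDir)
}

.loadCohortFromPaths <- function(paths) {
  phenotypes <- readPhenotypes(paths$phenotypes)
  ids <- phenotypes$subject_id
  series <- stats::setNames(lapply(ids, function(id)
    readTimeSeriesTSV(file.path(paths$seriesDir, paste0(id, ".tsv")))), ids)
  labels <- nodeLabels(series[[1]])
  for (id in ids)
    if (!identical(nodeLabels(series[[id]]), labels))
      stop(sprintf("subject '%s': node labels differ from the first subject",
                   id))
  motion <- stats::setNames(lapply(ids, function(id)
    readMotionTrace(file.path(paths$motionDir, paste0(id, ".tsv")))), ids)
  list(phenotypes = phenotypes, series = series, motion = motion,
       nuisance = NULL, groundTruth = NULL)
}

.configFingerprint <- function(config) {
  cfg <- config[setdiff(names(config), "outDir")]
  if (!is.null(cfg$cohort)) {
    sp <- cfg$cohort
    cfg$cohort <- list(
      nSubjects = sp@nSubjects, nTimepoints = sp@nTimepoints,
      samplingInterval = sp@samplingInterval, nodeLabels = sp@nodeLabels,
      covarianceDesign = as.vector(sp@covarianceDesign),
      arCoefficient = sp@arCoefficient, couplingPlan = sp@couplingPlan,
      behaviorNoiseSd = sp@behaviorNoiseSd, mpiIntercept = sp@mpiIntercept,
      ageRangeYounger = sp@ageRangeYounger, ageRangeOlder = sp@ageRangeOlder,
      ageMpiSlopeOlder = sp@ageMpiSlopeOlder,
      maleProportion = sp@maleProportion, stepSdMm = sp@stepSdMm,
      stepSdDeg = sp@stepSdDeg, seed = sp@seed)
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.groupSummary <- function(phenotypes) {
  data.frame(
    n = nrow(phenotypes),
    n_male = sum(phenotypes$gender == "M"),
    n_female = sum(phenotypes$gender == "F"),
    age_mean = mean(phenotypes$age), age_sd = stats::sd(phenotypes$age),
    age_min = min(phenotypes$age), age_max = max(phenotypes$age),
    mpi_mean = mean(phenotypes$mpi), mpi_sd = stats::sd(phenotypes$mpi),
    mpi_min = min(phenotypes$mpi), mpi_max = max(phenotypes$mpi)
  )
}

.demographics <- function(phenotypes, split, tMode) {
  older <- phenotypes[split$assignment[phenotypes$subject_id] == "older", ]
  younger <- phenotypes[split$assignment[phenotypes$subject_id] == "younger", ]
  tab <- rbind(
    cbind(group = "total", .groupSummary(phenotypes)),
    cbind(group = "older", .groupSummary(older)),
    cbind(group = "younger", .groupSummary(younger)))
  genderCounts <- matrix(
    c(sum(older$gender == "M"), sum(younger$gender == "M"),
      sum(older$gender == "F"), sum(younger$gender == "F")),
    2, 2, dimnames = list(c("older", "younger"), c("M", "F")))
  list(
    table = tab,
    gender_counts = genderCounts,
    gender_chi2 = chiSquare2x2(genderCounts),
    age_t = twoSampleT(older$age, younger$age, mode = tMode),
    mpi_t = twoSampleT(older$mpi, younger$mpi, mode = tMode),
    age_mpi_all = pearsonCorrelation(phenotypes$age, phenotypes$mpi),
    age_mpi_older = pearsonCorrelation(older$age, older$mpi),
    age_mpi_younger = pearsonCorrelation(younger$age, younger$mpi)
  )
}

.stageFail <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed for subject '%s': %s",
                 stage, id, conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: cohort simulation or loading; motion QC with
#' exclusion of high-motion subjects; per-subject preprocessing (discard,
#' detrend, bandpass, nuisance regression on the six motion parameters
#' plus any ventricle/white-matter signals); connectivity and degree
#' centrality; median split by age; within-group hub identification and
#' edge screening (group analyses are strictly within-group — no pooled
#' between-group connectivity contrast is computed); demographic and
#' motion statistics. With a fixed seed in the cohort spec the report is
#' bit-identical across runs. When `config$outDir` is set, every
#' intermediate is persisted there as TSV/JSON.
#'
#' @param config list from [pipelineConfig()].
#' @return A run report: list with `phenotypes`, `split`, `motionQC`,
#'   `motionComparison`, `connectivity` (per subject), `dc` (subject x
#'   node), `edgeWeights` (subject x edge), `hubTables` and `edgeTables`
#'   (per group), `demographics`, `excludedSubjects`, `provenance`.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(cohort = CohortSpec(nSubjects = 16, seed = 1))
#' rep <- runPipeline(cfg)
#' rep$demographics$table
#' }
#' @export
runPipeline <- function(config) {
  input <- if (!is.null(config$cohort)) generateCohort(config$cohort)
           else .loadCohortFromPaths(config$paths)
  phenotypes <- input$phenotypes
  ids <- phenotypes$subject_id

  qc <- motionQCTable(input$motion, config$transLimit, config$rotLimit)
  excluded <- qc$subject_id[qc$excluded]
  keep <- setdiff(ids, excluded)
  if (length(keep) < 8)
    stop("fewer than 8 subjects survive motion exclusion")
  phenotypes <- phenotypes[phenotypes$subject_id %in% keep, ]

  connectivity <- stats::setNames(vector("list", length(keep)), keep)
  for (id in keep) {
    nuis <- cbind(seriesData(input$motion[[id]]),
                  if (!is.null(input$nuisance)) input$nuisance[[id]])
    nuisNames <- c(.motionColumns,
                   if (!is.null(input$nuisance))
                     colnames(input$nuisance[[id]]))
    pre <- .stageFail("preprocess", id,
      preprocessSeries(input$series[[id]],
                       NuisanceSet(nuis, nuisNames),
                       nDiscard = config$nDiscard, lowHz = config$lowHz,
                       highHz = config$highHz,
                       filterNuisance = config$filterNuisance))
    connectivity[[id]] <- .stageFail("connectivity", id,
      computeConnectivity(pre, clip = TRUE))
  }

  dc <- dcMatrix(connectivity)
  ew <- edgeWeightMatrix(connectivity)
  split <- medianSplit(phenotypes)

  hubTables <- list()
  edgeTables <- list()
  for (g in c("older", "younger")) {
    inG <- split$assignment[phenotypes$subject_id] == g
    phG <- phenotypes[inG, ]
    hubTables[[g]] <- identifyHubs(dc[phG$subject_id, , drop = FALSE], phG,
                                   alpha = config$alpha)
    edgeTables[[g]] <- screenEdges(ew[phG$subject_id, , drop = FALSE], phG,
                                   alpha = config$alpha)
  }

  qcKept <- qc[qc$subject_id %in% keep, ]
  grp <- split$assignment[qcKept$subject_id]
  motionComparison <- list(
    translation = compareGroupMotion(qcKept[grp == "older", ],
                                     qcKept[grp == "younger", ],
                                     "translation", mode = config$tMode),
    rotation = compareGroupMotion(qcKept[grp == "older", ],
                                  qcKept[grp == "younger", ],
                                  "rotation", mode = config$tMode))

  report <- list(
    phenotypes = phenotypes,
    split = split,
    motionQC = qc,
    motionComparison = motionComparison,
    connectivity = connectivity,
    dc = dc,
    edgeWeights = ew,
    hubTables = hubTables,
    edgeTables = edgeTables,
    demographics = .demographics(phenotypes, split, config$tMode),
    excludedSubjects = excluded,
    groundTruth = input$groundTruth,
    provenance = list(
      config_hash = .configFingerprint(config),
      seed = if (!is.null(config$cohort)) config$cohort@seed else NA,
      package_version = as.character(utils::packageVersion("masticNet")),
      r_version = R.version.string)
  )

  if (!is.null(config$outDir)) .persistReport(report, config)
  report
}

.persistReport <- function(report, config) {
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "connectivity"), showWarnings = FALSE)
  writePhenotypes(report$phenotypes, file.path(out, "phenotypes.tsv"))
  .writeTSV(report$motionQC, file.path(out, "motion_qc.tsv"))
  for (id in names(report$connectivity)) {
    writeConnectivityMatrix(report$connectivity[[id]],
                            file.path(out, "connectivity",
                                      paste0(id, "_r.tsv")))
    writeWeightMatrixTSV(report$connectivity[[id]],
                         file.path(out, "connectivity",
                                   paste0(id, "_weight.tsv")))
  }
  .writeTSV(data.frame(subject_id = rownames(report$dc), report$dc,
                       check.names = FALSE),
            file.path(out, "degree_centrality.tsv"))
  for (g in names(report$hubTables)) {
    .writeTSV(report$hubTables[[g]],
              file.path(out, sprintf("hubs_%s.tsv", g)))
    .writeTSV(report$edgeTables[[g]],
              file.path(out, sprintf("edges_%s.tsv", g)))
  }
  .writeTSV(report$demographics$table, file.path(out, "demographics.tsv"))
  jsonlite::write_json(
    list(gender_chi2 = report$demographics$gender_chi2,
         age_t = report$demographics$age_t,
         mpi_t = report$demographics$mpi_t,
         age_mpi_all = report$demographics$age_mpi_all,
         age_mpi_older = report$demographics$age_mpi_older,
         age_mpi_younger = report$demographics$age_mpi_younger,
         motion_comparison = report$motionComparison,
         split_threshold_age = report$split$threshold_age,
         excluded_subjects = report$excludedSubjects,
         provenance = report$provenance),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$groundTruth))
    writeGroundTruthJSON(report$groundTruth,
                         file.path(out, "ground_truth.json"))
  invisible(out)
}
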