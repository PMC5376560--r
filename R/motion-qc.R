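.frameDisplacements <- function(trace) {
  d <- diff(trace@data)
  list(
    translation = sqrt(rowSums(d[, 1:3, drop = FALSE]^2)),
    rotation = sqrt(rowSums(d[, 4:6, drop = FALSE]^2))
  )
}

#' Mean frame-to-frame displacement
#'
#' For each frame i >= 2 the translational displacement is the Euclidean
#' norm of the change in (tx, ty, tz) relative to frame i - 1, and
#' analogously for rotations on (rx, ry, rz) in degrees. The index is the
#' mean over the `timepoints - 1` frame-to-frame displacements. Only
#' differences matter, so the index is invariant to a constant offset of
#' the whole trace.
#'
#' @param trace a [MotionTrace-class].
#' @return Named numeric vector `c(mean_translation_mm, mean_rotation_deg)`.
#' @examples
#' tr <- MotionTrace(cbind(seq(0, 1, length.out = 11), 0, 0, 0, 0, 0))
#' meanDisplacement(tr)  # 0.1 mm translation per frame
#' @export
meanDisplacement <- function(trace) {
  stopifnot(is(trace, "MotionTrace"))
  disp <- .frameDisplacements(trace)
  c(mean_translation_mm = mean(disp$translation),
    mean_rotation_deg = mean(disp$rotation))
}

#' Motion summary and exclusion decision
#'
#' Computes the mean and maximal frame-to-frame displacement for
#' translation and rotation and applies the exclusion rule: a subject is
#' retained only when the maximal displacement stays strictly below 1.5 mm
#' in translation and 1.5 degrees in rotation (a maximum exactly at the
#' limit is excluded).
#'
#' @param trace a [MotionTrace-class].
#' @param transLimit,rotLimit positive exclusion limits (mm, degrees).
#' @return One-row data.frame with columns `mean_translation_mm`,
#'   `mean_rotation_deg`, `max_translation_mm`, `max_rotation_deg`,
#'   `excluded`.
#' @export
checkExclusion <- function(trace, transLimit = 1.5, rotLimit = 1.5) {
  stopifnot(is(trace, "MotionTrace"))
  if (transLimit <= 0 || rotLimit <= 0)
    stop("exclusion limits must be positive")
  disp <- .frameDisplacements(trace)
  maxT <- max(disp$translation)
  maxR <- max(disp$rotation)
  data.frame(
    mean_translation_mm = mean(disp$translation),
    mean_rotation_deg = mean(disp$rotation),
    max_translation_mm = maxT,
    max_rotation_deg = maxR,
    excluded = maxT >= transLimit || maxR >= rotLimit
  )
}

#' Compare mean displacement between two groups
#'
#' Two-tailed two-sample t test on the per-subject mean-displacement
#' indices of one modality, delegating to [twoSampleT()].
#'
#' @param summariesA,summariesB data.frames as returned by
#'   [checkExclusion()] (one row per subject), or any data.frame with the
#'   required mean-displacement column.
#' @param modality `"translation"` or `"rotation"`.
#' @param mode `"welch"` (default) or `"pooled"`.
#' @return List with `t`, `df`, `p_two_tailed`.
#' @export
compareGroupMotion <- function(summariesA, summariesB,
                               modality = c("translation", "rotation"),
                               mode = c("welch", "pooled")) {
  modality <- match.arg(modality)
  col <- if (modality == "translation") "mean_translation_mm"
         else "mean_rotation_deg"
  a <- summariesA[[col]]
  b <- summariesB[[col]]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 subjects")
  twoSampleT(a, b, mode = match.arg(mode))
}

#' Motion QC table for a set of subjects
#'
#' @param motion named list of [MotionTrace-class] objects keyed by subject
#'   id.
#' @param transLimit,rotLimit exclusion limits passed to [checkExclusion()].
#' @return data.frame with one row per subject (`subject_id` first).
#' @export
motionQCTable <- function(motion, transLimit = 1.5, rotLimit = 1.5) {
  rows <- lapply(names(motion), function(id) {
    cbind(subject_id = id,
          checkExclusion(motion[[id]], transLimit, rotLimit))
  })
  do.call(rbind, rows)
}
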