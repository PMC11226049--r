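#' Assemble a longitudinal survival cohort from its two component tables
#'
#' A cohort is stored as two data frames, mirroring the delimited-text layout
#' used for import/export: a survival table with one row per subject (baseline
#' covariates, observed time, event indicator) and a longitudinal table with
#' one row per subject-visit (time-varying covariate values). Covariates are
#' read at analysis time by last observation carried forward (LOCF).
#'
#' @param survival data frame with columns `subject_id`, `age`, `sex`,
#'   `etoh`, `biliary`, `chol`, `time` (observed follow-up, years), `event`
#'   (0/1 death indicator).
#' @param longitudinal data frame with columns `subject_id`, `time` (years
#'   since entry), `meld_na`, `albumin`, `decomp` (cumulative count of
#'   decompensating events), `hcc` (0/1, one-way).
#' @return An object of class `lm_cohort`.
#' @export
as_cohort <- function(survival, longitudinal) {
  coh <- structure(list(survival = as.data.frame(survival),
                        longitudinal = as.data.frame(longitudinal)),
                   class = "lm_cohort")
  validate_cohort(coh)
  coh
}

#' Validate the internal consistency of a cohort
#'
#' Checks the per-subject invariants the downstream landmarking machinery
#' relies on: positive observed times, 0/1 event indicators, strictly
#' increasing visit times that never exceed the observed time, a
#' non-decreasing decompensation count and a one-way HCC switch.
#'
#' @param cohort an `lm_cohort`.
#' @return `cohort`, invisibly; errors on the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  sv <- cohort$survival
  lg <- cohort$longitudinal
  need_sv <- c("subject_id", "age", "sex", "etoh", "biliary", "chol",
               "time", "event")
  need_lg <- c("subject_id", "time", "meld_na", "albumin", "decomp", "hcc")
  if (!all(need_sv %in% names(sv)))
    stop("survival table must have columns: ",
         paste(need_sv, collapse = ", "), call. = FALSE)
  if (!all(need_lg %in% names(lg)))
    stop("longitudinal table must have columns: ",
         paste(need_lg, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sv$subject_id))
    stop("duplicated subject_id in survival table", call. = FALSE)
  if (any(sv$time <= 0)) stop("observed times must be > 0", call. = FALSE)
  if (!all(sv$event %in% c(0, 1)))
    stop("event indicator must be 0/1", call. = FALSE)
  if (nrow(lg)) {
    if (!all(lg$subject_id %in% sv$subject_id))
      stop("longitudinal rows for unknown subjects", call. = FALSE)
    Tmap <- sv$time[match(lg$subject_id, sv$subject_id)]
    if (any(lg$time > Tmap + 1e-12))
      stop("measurement times must be <= observed time", call. = FALSE)
    for (sid in unique(lg$subject_id)) {
      m <- lg[lg$subject_id == sid, , drop = FALSE]
      if (is.unsorted(m$time, strictly = TRUE))
        stop("measurement times must be strictly increasing (subject ",
             sid, ")", call. = FALSE)
      if (is.unsorted(m$decomp))
        stop("decomp count must be non-decreasing (subject ", sid, ")",
             call. = FALSE)
      if (is.unsorted(m$hcc) || !all(m$hcc %in% c(0, 1)))
        stop("hcc must be a 0/1 one-way switch (subject ", sid, ")",
             call. = FALSE)
    }
  }
  invisible(cohort)
}

#' @export
print.lm_cohort <- function(x, ...) {
  n <- nrow(x$survival)
  cat("Longitudinal survival cohort: ", n, " subjects, ",
      nrow(x$longitudinal), " measurements\n", sep = "")
  cat("  events: ", sum(x$survival$event),
      sprintf(" (%.1f%%)", 100 * mean(x$survival$event)),
      ", median follow-up ",
      sprintf("%.2f", stats::median(x$survival$time)), " yr\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort an `lm_cohort`.
#' @return integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$survival)

#' Write a cohort to two delimited text tables
#'
#' Emits `survival.csv` and `longitudinal.csv` (comma-separated, header row,
#' times in years as decimals) under `dir`.
#'
#' @param cohort an `lm_cohort`.
#' @param dir output directory, created if absent.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- file.path(dir, c("survival.csv", "longitudinal.csv"))
  utils::write.csv(cohort$survival, fs[1], row.names = FALSE)
  utils::write.csv(cohort$longitudinal, fs[2], row.names = FALSE)
  invisible(fs)
}

#' Read a cohort from its two delimited text tables
#'
#' @param survival_file,longitudinal_file paths to the tables written by
#'   [write_cohort()] (or any files with the same columns).
#' @return An `lm_cohort`.
#' @export
read_cohort <- function(survival_file, longitudinal_file) {
  as_cohort(utils::read.csv(survival_file),
            utils::read.csv(longitudinal_file))
}

#' Restrict a cohort to a subset of subjects
#' @param cohort an `lm_cohort`.
#' @param ids subject ids to keep.
#' @return An `lm_cohort` with only those subjects.
#' @export
subset_cohort <- function(cohort, ids) {
  structure(list(
    survival = cohort$survival[cohort$survival$subject_id %in% ids, ,
                               drop = FALSE],
    longitudinal = cohort$longitudinal[
      cohort$longitudinal$subject_id %in% ids, , drop = FALSE]
  ), class = "lm_cohort")
}
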