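# Domain types for the longitudinal high-risk offspring cohort.

#' Names of the time-varying antecedent indicators
#'
#' The nine binary time-varying predictors tracked for each offspring:
#' clinically significant subthreshold symptom presentations (activation,
#' depression, sleep, substance, anxiety) and lifetime antecedent non-mood
#' diagnoses (substance use, sleep, anxiety, neurodevelopmental disorder).
#' Each is dated by its age of first onset and enters the models as a lagged
#' 0/1 status.
#'
#' @return Character vector of length nine.
#' @export
mood_indicators <- function() {
  c("subthreshold_activation", "subthreshold_depression", "subthreshold_sleep",
    "subthreshold_substance", "subthreshold_anxiety",
    "substance_use", "sleep", "anxiety", "neurodevelopmental")
}

#' Construct a cohort subject
#'
#' One individual in the high-risk cohort: time-fixed covariates, ages of
#' first onset of the antecedent indicators, ages of antecedent major and
#' minor mood episodes, and the outcome (age at diagnosis of major mood
#' disorder, or age at last follow-up visit for censored subjects).
#'
#' Onset or episode ages at or after `outcome_age` are permitted in the
#' record but are ignored by every downstream computation: only antecedents
#' occurring strictly before the outcome may influence a prediction.
#'
#' @param id Subject identifier (coerced to character).
#' @param sex_male 0/1, sex at birth.
#' @param parental_lithium_response 0/1, parental response to lithium
#'   prophylaxis.
#' @param parental_onset_age Parental age of onset of bipolar disorder, in
#'   years (positive).
#' @param abuse Childhood physical/sexual abuse: one of `"yes"`, `"no"`,
#'   `"missing"` (the instrument is only administered from age 13, so
#'   missingness is an explicit level, not an exclusion).
#' @param outcome_age Age in years at diagnosis (if `event == 1`) or at the
#'   last follow-up visit (if `event == 0`).
#' @param event 1 if diagnosed with a major mood disorder, 0 if censored.
#' @param onset_ages Named numeric vector mapping indicator names (a subset
#'   of [mood_indicators()]) to the age of first onset; omit indicators that
#'   never onset.
#' @param major_episode_ages,minor_episode_ages Numeric vectors of ages of
#'   antecedent major / minor mood episodes.
#'
#' @return An object of class `"mood_subject"`.
#' @export
#' @examples
#' subject("s1", sex_male = 1, parental_lithium_response = 0,
#'         parental_onset_age = 24, abuse = "no",
#'         outcome_age = 19.2, event = 1,
#'         onset_ages = c(anxiety = 12.5))
subject <- function(id, sex_male, parental_lithium_response, parental_onset_age,
                    abuse, outcome_age, event,
                    onset_ages = numeric(0),
                    major_episode_ages = numeric(0),
                    minor_episode_ages = numeric(0)) {
  stopifnot(length(id) == 1)
  if (!is.numeric(outcome_age) || length(outcome_age) != 1 || outcome_age <= 0)
    stop("'outcome_age' must be a single positive number", call. = FALSE)
  if (!event %in% c(0, 1)) stop("'event' must be 0 or 1", call. = FALSE)
  if (!sex_male %in% c(0, 1)) stop("'sex_male' must be 0 or 1", call. = FALSE)
  if (!parental_lithium_response %in% c(0, 1))
    stop("'parental_lithium_response' must be 0 or 1", call. = FALSE)
  if (!is.numeric(parental_onset_age) || parental_onset_age <= 0)
    stop("'parental_onset_age' must be positive", call. = FALSE)
  abuse <- match.arg(abuse, c("yes", "no", "missing"))
  if (length(onset_ages)) {
    bad <- setdiff(names(onset_ages), mood_indicators())
    if (length(bad))
      stop("unknown indicator name(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(onset_ages <= 0)) stop("onset ages must be positive", call. = FALSE)
  }
  structure(list(
    id = as.character(id),
    sex_male = as.numeric(sex_male),
    parental_lithium_response = as.numeric(parental_lithium_response),
    parental_onset_age = as.numeric(parental_onset_age),
    abuse = abuse,
    onset_ages = onset_ages,
    major_episode_ages = as.numeric(major_episode_ages),
    minor_episode_ages = as.numeric(minor_episode_ages),
    outcome_age = as.numeric(outcome_age),
    event = as.numeric(event)
  ), class = "mood_subject")
}

#' Construct a cohort
#'
#' @param subjects List of [subject()] objects with unique ids.
#' @return An object of class `"mood_cohort"` (a list of subjects).
#' @export
cohort <- function(subjects) {
  if (!all(vapply(subjects, inherits, logical(1), "mood_subject")))
    stop("all elements must be 'mood_subject' objects", call. = FALSE)
  ids <- vapply(subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  names(subjects) <- ids
  structure(subjects, class = "mood_cohort")
}

#' @export
print.mood_cohort <- function(x, ...) {
  ev <- vapply(x, `[[`, numeric(1), "event")
  cat(sprintf("<mood_cohort> %d subjects, %d events (%.1f%%), %d censored\n",
              length(x), sum(ev), 100 * mean(ev), sum(ev == 0)))
  invisible(x)
}

#' @export
print.mood_subject <- function(x, ...) {
  cat(sprintf("<mood_subject> %s: %s at age %.2f, %d indicator onset(s)\n",
              x$id, if (x$event == 1) "diagnosed" else "censored",
              x$outcome_age, length(x$onset_ages)))
  invisible(x)
}

cohort_events <- function(cohort) vapply(cohort, `[[`, numeric(1), "event")
cohort_times  <- function(cohort) vapply(cohort, `[[`, numeric(1), "outcome_age")

#' Read a cohort from delimited text files
#'
#' Reads the three-table on-disk representation: a subjects table (one row
#' per subject: `id, sex_male, parental_lithium_response, parental_onset_age,
#' abuse, outcome_age, event`), an onsets table (`id, indicator_name,
#' onset_age`; absent row = indicator never onset), and an episodes table
#' (`id, kind, episode_age` with `kind` in `major`/`minor`). All files are
#' CSV with a header row.
#'
#' @param subjects_file,onsets_file,episodes_file Paths to the CSV files.
#'   `onsets_file` and `episodes_file` may be `NULL` when there are none.
#' @return A [cohort()].
#' @export
read_cohort <- function(subjects_file, onsets_file = NULL, episodes_file = NULL) {
  subj <- utils::read.csv(subjects_file, stringsAsFactors = FALSE)
  need <- c("id", "sex_male", "parental_lithium_response", "parental_onset_age",
            "abuse", "outcome_age", "event")
  miss <- setdiff(need, names(subj))
  if (length(miss))
    stop("subjects file missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  onsets <- if (!is.null(onsets_file))
    utils::read.csv(onsets_file, stringsAsFactors = FALSE)
  else data.frame(id = character(0), indicator_name = character(0), onset_age = numeric(0))
  eps <- if (!is.null(episodes_file))
    utils::read.csv(episodes_file, stringsAsFactors = FALSE)
  else data.frame(id = character(0), kind = character(0), episode_age = numeric(0))
  subj$id <- as.character(subj$id)
  onsets$id <- as.character(onsets$id)
  eps$id <- as.character(eps$id)
  cohort(lapply(seq_len(nrow(subj)), function(i) {
    r <- subj[i, ]
    on <- onsets[onsets$id == r$id, ]
    ep <- eps[eps$id == r$id, ]
    subject(r$id, r$sex_male, r$parental_lithium_response, r$parental_onset_age,
            r$abuse, r$outcome_age, r$event,
            onset_ages = stats::setNames(on$onset_age, on$indicator_name),
            major_episode_ages = ep$episode_age[ep$kind == "major"],
            minor_episode_ages = ep$episode_age[ep$kind == "minor"])
  }))
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: writes `subjects.csv`, `onsets.csv` and
#' `episodes.csv` under `dir`.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- do.call(rbind, lapply(cohort, function(s) data.frame(
    id = s$id, sex_male = s$sex_male,
    parental_lithium_response = s$parental_lithium_response,
    parental_onset_age = s$parental_onset_age, abuse = s$abuse,
    outcome_age = s$outcome_age, event = s$event)))
  onsets <- do.call(rbind, lapply(cohort, function(s) {
    if (!length(s$onset_ages)) return(NULL)
    data.frame(id = s$id, indicator_name = names(s$onset_ages),
               onset_age = unname(s$onset_ages))
  }))
  if (is.null(onsets))
    onsets <- data.frame(id = character(0), indicator_name = character(0),
                         onset_age = numeric(0))
  eps <- do.call(rbind, lapply(cohort, function(s) {
    rbind(
      if (length(s$major_episode_ages))
        data.frame(id = s$id, kind = "major", episode_age = s$major_episode_ages),
      if (length(s$minor_episode_ages))
        data.frame(id = s$id, kind = "minor", episode_age = s$minor_episode_ages))
  }))
  if (is.null(eps))
    eps <- data.frame(id = character(0), kind = character(0), episode_age = numeric(0))
  paths <- file.path(dir, c("subjects.csv", "onsets.csv", "episodes.csv"))
  utils::write.csv(subj, paths[1], row.names = FALSE)
  utils::write.csv(onsets, paths[2], row.names = FALSE)
  utils::write.csv(eps, paths[3], row.names = FALSE)
  invisible(paths)
}
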