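# Expansion of a cohort into lagged person-period format.
#
# Each subject contributes one row per interval in which they are at risk;
# the binary response `event_in_interval` turns discrete survival estimation
# into a binary-outcome problem. All time-varying covariates are lagged by
# one interval: the value carried by interval k reflects status as of the
# end of interval k-1, so a prediction for k uses no information from k
# itself (reverse-causality guard).

pp_id_cols <- c("subject_id", "interval_index", "interval_start",
                "interval_end", "event_in_interval")

#' Covariate column names of a person-period table
#'
#' Column order is fixed: the time-fixed block (sex, parental lithium
#' response, parental onset age, abuse dummies with "no" as reference),
#' the nine lagged antecedent indicators, the two lagged cumulative episode
#' counts, and `time_input` (the interval midpoint age in years, so models
#' may condition on time directly).
#'
#' @return Character vector of covariate column names.
#' @export
pp_covariate_names <- function() {
  c("sex_male", "parental_lithium_response", "parental_onset_age",
    "abuse_yes", "abuse_missing", mood_indicators(),
    "major_episodes", "minor_episodes", "time_input")
}

# continuous columns (candidates for model-side standardization)
pp_continuous_names <- function() {
  c("parental_onset_age", "major_episodes", "minor_episodes", "time_input")
}

#' Lagged antecedent indicator status
#'
#' Status of a time-varying 0/1 indicator as carried by interval k: 1 iff
#' the indicator's first onset occurred strictly before the start of
#' interval k (i.e. the status at the end of interval k-1). Onsets at or
#' after the subject's outcome age never contribute — only antecedents count.
#'
#' @param subject A [subject()].
#' @param name One of [mood_indicators()].
#' @param k Interval index (1-based).
#' @param scheme An [interval_scheme()].
#' @return 0 or 1.
#' @export
lagged_indicator <- function(subject, name, k, scheme) {
  if (!name %in% mood_indicators())
    stop("unknown indicator name: ", name, call. = FALSE)
  onset <- subject$onset_ages[name]
  if (is.null(onset) || length(onset) == 0 || is.na(onset)) return(0)
  onset <- unname(onset)
  if (onset >= subject$outcome_age) return(0)   # antecedents only
  as.numeric(onset < interval_start(scheme, k))
}

#' Lagged cumulative mood-episode count
#'
#' Number of antecedent major or minor mood episodes experienced strictly
#' before the start of interval k (and strictly before the outcome).
#'
#' @inheritParams lagged_indicator
#' @param kind `"major"` or `"minor"`.
#' @return Non-negative integer count.
#' @export
lagged_cumulative_episodes <- function(subject, kind = c("major", "minor"), k, scheme) {
  kind <- match.arg(kind)
  ages <- if (kind == "major") subject$major_episode_ages else subject$minor_episode_ages
  ages <- ages[ages < subject$outcome_age]
  sum(ages < interval_start(scheme, k))
}

# full covariate vector for subject at interval k (lagged convention)
subject_covariate_row <- function(subject, k, scheme) {
  ind <- vapply(mood_indicators(), function(nm)
    lagged_indicator(subject, nm, k, scheme), numeric(1))
  c(sex_male = subject$sex_male,
    parental_lithium_response = subject$parental_lithium_response,
    parental_onset_age = subject$parental_onset_age,
    abuse_yes = as.numeric(subject$abuse == "yes"),
    abuse_missing = as.numeric(subject$abuse == "missing"),
    ind,
    major_episodes = lagged_cumulative_episodes(subject, "major", k, scheme),
    minor_episodes = lagged_cumulative_episodes(subject, "minor", k, scheme),
    time_input = interval_mid(scheme, k))
}

# number of at-risk intervals a subject contributes: events include the
# interval containing the event; censored subjects only intervals fully
# survived (interval_end <= censoring age).
n_at_risk_intervals <- function(subject, scheme) {
  if (subject$event == 1) {
    k <- interval_index_of(scheme, subject$outcome_age)
    if (is.na(k))
      stop("event age ", subject$outcome_age, " of subject '", subject$id,
           "' falls outside the interval scheme", call. = FALSE)
    k
  } else {
    sum(scheme$boundaries[-1] <= subject$outcome_age + 1e-9)
  }
}

#' Expand a cohort into a person-period table
#'
#' One row per subject per at-risk interval. A subject diagnosed at age t
#' contributes rows for every interval up to and including the one
#' containing t, with `event_in_interval = 1` only in that last row. A
#' censored subject contributes rows only for intervals fully survived
#' (`interval_end <=` censoring age), all with `event_in_interval = 0`.
#'
#' @param cohort A [cohort()]; every subject must have
#'   `outcome_age >= scheme$min_age`.
#' @param scheme An [interval_scheme()].
#' @return A `data.frame` of class `"person_period_table"` with the id/
#'   response columns of `pp_id_cols` followed by [pp_covariate_names()];
#'   the scheme is attached as attribute `"scheme"`.
#' @export
expand_person_periods <- function(cohort, scheme) {
  bad <- names(cohort)[cohort_times(cohort) < scheme$min_age]
  if (length(bad))
    stop("subject(s) with outcome_age below the scheme minimum age: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rows <- lapply(cohort, function(s) {
    nk <- n_at_risk_intervals(s, scheme)
    if (nk == 0) return(NULL)
    cov <- t(vapply(seq_len(nk), function(k) subject_covariate_row(s, k, scheme),
                    numeric(length(pp_covariate_names()))))
    ev <- numeric(nk)
    if (s$event == 1) ev[nk] <- 1
    data.frame(subject_id = s$id,
               interval_index = seq_len(nk),
               interval_start = interval_start(scheme, seq_len(nk)),
               interval_end = interval_end(scheme, seq_len(nk)),
               event_in_interval = ev,
               cov, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else {
    empty <- as.data.frame(matrix(numeric(0), 0,
                                  length(pp_id_cols) + length(pp_covariate_names())))
    names(empty) <- c(pp_id_cols, pp_covariate_names())
    empty$subject_id <- character(0)
    empty
  }
  attr(tab, "scheme") <- scheme
  class(tab) <- c("person_period_table", "data.frame")
  tab
}

# Covariate rows for ALL intervals of the scheme (not just at-risk ones),
# used to form whole-horizon predicted survival curves for test subjects.
# The lag convention freezes each covariate at its last pre-outcome value.
prediction_rows <- function(subject, scheme) {
  ks <- seq_len(scheme$n_intervals)
  cov <- t(vapply(ks, function(k) subject_covariate_row(subject, k, scheme),
                  numeric(length(pp_covariate_names()))))
  data.frame(subject_id = subject$id, interval_index = ks,
             interval_start = interval_start(scheme, ks),
             interval_end = interval_end(scheme, ks),
             event_in_interval = NA_real_, cov, row.names = NULL)
}

#' Write a person-period table and its scheme sidecar
#'
#' Writes the table as CSV (deterministic column order) plus a JSON sidecar
#' recording the interval scheme and the lagging convention.
#'
#' @param table A `person_period_table` from [expand_person_periods()].
#' @param file Output CSV path; the sidecar is written next to it as
#'   `<file>.scheme.json`.
#' @return Invisibly, the two paths.
#' @export
write_person_periods <- function(table, file) {
  utils::write.csv(as.data.frame(table)[, c(pp_id_cols, pp_covariate_names())],
                   file, row.names = FALSE)
  scheme <- attr(table, "scheme")
  sidecar <- paste0(file, ".scheme.json")
  jsonlite::write_json(list(
    width = scheme$width, min_age = scheme$min_age, max_age = scheme$max_age,
    boundaries = scheme$boundaries,
    lagging = "time-varying covariates reflect status strictly before interval start",
    censoring_convention = "censored subjects at risk only in fully survived intervals"
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(file, sidecar))
}
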