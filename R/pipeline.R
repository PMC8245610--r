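# End-to-end experiment: expand -> fit both hazard models -> stratified
# cross-validated, censoring-aware evaluation -> report.

#' Experiment configuration
#'
#' @param widths Interval widths (years) to evaluate; 1, 3 and 5 correspond
#'   to 1-, 3- and 5-year-ahead prediction.
#' @param folds Number of stratified cross-validation folds.
#' @param seed Master seed; fold assignment, PLANN initialization and any
#'   other randomness derive from it deterministically.
#' @param min_age Left anchor of every interval scheme (enrolment age).
#' @param max_age Upper age bound of the schemes; `NULL` = the cohort's
#'   maximum observed outcome age (rounded up to the interval grid).
#' @param brier_ages Ages (years) at which Brier scores are computed and
#'   averaged.
#' @param thresholds Hazard thresholds for the confusion-metric grid; the
#'   Youden-optimal threshold is always evaluated in addition.
#' @param brier_weighting `"ipcw"` or `"unweighted"` for the headline
#'   Brier scores (both are always included in the per-fold breakdown).
#' @param glm_ridge Ridge penalty passed to [fit_hazard_glm()].
#' @param plann A [plann_control()]; its seed is re-derived per fold from
#'   `seed`.
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(widths = c(1, 3, 5), folds = 10, seed = 1,
                              min_age = 5, max_age = NULL,
                              brier_ages = c(15, 20, 25),
                              thresholds = c(0.05, 0.10, 0.15, 0.20),
                              brier_weighting = c("ipcw", "unweighted"),
                              glm_ridge = 1e-6,
                              plann = plann_control()) {
  if (any(widths <= 0)) stop("'widths' must be positive", call. = FALSE)
  if (folds < 2) stop("'folds' must be >= 2", call. = FALSE)
  structure(list(widths = widths, folds = folds, seed = seed,
                 min_age = min_age, max_age = max_age,
                 brier_ages = brier_ages, thresholds = thresholds,
                 brier_weighting = match.arg(brier_weighting),
                 glm_ridge = glm_ridge, plann = plann),
            class = "experiment_config")
}

# evaluate one fitted model on one test fold; returns scalar metrics plus
# per-interval vectors (NA where a risk set was degenerate)
eval_fold_model <- function(preds, config, G) {
  nk <- preds$scheme$n_intervals
  safe <- function(expr) tryCatch(expr,
    plannsurv_undefined_metric = function(e) NA_real_)
  ages <- config$brier_ages[config$brier_ages <= max(preds$scheme$boundaries)]
  auc <- vapply(seq_len(nk), function(k) safe(interval_auc(preds, k)), numeric(1))
  thr_rows <- list()
  for (thr in config$thresholds) {
    cm <- lapply(seq_len(nk), function(k) tryCatch(
      confusion_at_threshold(preds, k, thr),
      plannsurv_undefined_metric = function(e) NULL))
    thr_rows[[sprintf("%.2f", thr)]] <- cm
  }
  opt <- lapply(seq_len(nk), function(k) tryCatch({
    th <- optimal_threshold(preds, k)
    c(confusion_at_threshold(preds, k, as.numeric(th)), threshold = as.numeric(th))
  }, plannsurv_undefined_metric = function(e) NULL))
  thr_rows[["optimal"]] <- opt
  list(
    c_index = safe(td_c_index(preds)),
    brier = vapply(ages, function(a)
      safe(brier_score(preds, a, config$brier_weighting, G)), numeric(1)),
    brier_ages = ages,
    mean_brier = safe(mean_brier(preds, ages, config$brier_weighting, G)),
    mean_brier_unweighted = safe(mean_brier(preds, ages, "unweighted")),
    interval_auc = auc,
    mean_auc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE),
    thresholds = thr_rows
  )
}

# average one confusion field across intervals within a fold, skipping
# undefined entries
cm_mean <- function(cm_list, field) {
  v <- vapply(cm_list, function(x) if (is.null(x)) NA_real_ else
    as.numeric(x[[field]]), numeric(1))
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Run the full model-comparison experiment
#'
#' For each interval width: expands the cohort into person-period format,
#' assigns stratified folds (stratified on the event indicator), and per
#' fold fits the discrete-time logistic model and PLANN on the training
#' folds only — input standardization and the censoring-distribution
#' estimate for IPCW are likewise confined to training data — then predicts
#' whole-horizon survival for the test fold and accumulates the
#' censoring-aware metrics. Metrics are averaged first across intervals
#' within a fold (where defined), then across folds; undefined cells are
#' excluded from means and counted, never imputed.
#'
#' @param cohort A [cohort()].
#' @param config An [experiment_config()].
#' @return An object of class `"evaluation_report"`: `descriptives` (the
#'   cohort summary of [descriptive_table()]), one entry per width under
#'   `$widths` with per-model summaries and a `per_fold` breakdown, and the
#'   config. Fully reproducible given the config seed.
#' @export
run_experiment <- function(cohort, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  max_age <- if (is.null(config$max_age)) max(cohort_times(cohort)) else config$max_age
  folds <- stratified_folds(cohort, config$folds, config$seed)
  out <- list()
  for (wi in seq_along(config$widths)) {
    w <- config$widths[wi]
    scheme <- interval_scheme(w, config$min_age, max_age + 1e-9)
    per_fold <- list()
    for (f in seq_len(config$folds)) {
      train <- cohort(unclass(cohort)[folds != f])
      test <- cohort(unclass(cohort)[folds == f])
      pp <- expand_person_periods(train, scheme)
      glm_fit <- fit_hazard_glm(pp, ridge = config$glm_ridge)
      pc <- config$plann
      pc$seed <- child_seed(config$seed, wi * 1000L + f)
      plann_fit <- fit_plann(pp, control = pc)
      G <- censoring_km(cohort_times(train), cohort_events(train))
      res <- lapply(list(survival = glm_fit, plann = plann_fit), function(m) {
        preds <- predict_survival_curves(m, test, scheme)
        eval_fold_model(preds, config, G)
      })
      per_fold[[f]] <- res
    }
    models <- list()
    for (m in c("survival", "plann")) {
      fm <- lapply(per_fold, `[[`, m)
      auc_fold <- vapply(fm, `[[`, numeric(1), "mean_auc")
      # per-interval AUC averaged across folds, then summarized
      auc_mat <- do.call(rbind, lapply(fm, `[[`, "interval_auc"))
      auc_by_int <- colMeans(auc_mat, na.rm = TRUE)
      auc_by_int[is.nan(auc_by_int)] <- NA
      thr_names <- names(fm[[1]]$thresholds)
      conf <- do.call(rbind, lapply(thr_names, function(tn) {
        vals <- vapply(c("accuracy", "specificity", "sensitivity", "ppv"),
                       function(fd) {
                         per <- vapply(fm, function(x)
                           cm_mean(x$thresholds[[tn]], fd), numeric(1))
                         if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
                       }, numeric(1))
        data.frame(threshold = tn, t(vals), row.names = NULL)
      }))
      models[[m]] <- list(
        c_index = mean(vapply(fm, `[[`, numeric(1), "c_index"), na.rm = TRUE),
        mean_brier = mean(vapply(fm, `[[`, numeric(1), "mean_brier"), na.rm = TRUE),
        mean_brier_unweighted =
          mean(vapply(fm, `[[`, numeric(1), "mean_brier_unweighted"), na.rm = TRUE),
        mean_auc = mean(auc_fold, na.rm = TRUE),
        sd_auc = stats::sd(auc_fold, na.rm = TRUE),
        auc_by_interval = auc_by_int,
        confusion = conf,
        n_undefined_auc = sum(is.na(auc_mat)))
    }
    out[[paste0("width_", w)]] <- list(width = w, scheme = scheme,
                                       models = models, per_fold = per_fold)
  }
  structure(list(descriptives = descriptive_table(cohort),
                 widths = out, folds = folds, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(performance_table(x), digits = 3)
  invisible(x)
}

#' Headline performance table of an evaluation report
#'
#' One row per metric (mean Brier score, c-index, mean AUC with its SD
#' across folds), one column per model x interval width.
#'
#' @param report An [run_experiment()] result.
#' @return A `data.frame`.
#' @export
performance_table <- function(report) {
  metrics <- c("mean_brier", "c_index", "mean_auc", "sd_auc")
  out <- data.frame(metric = c("Mean Brier score", "C-index", "Mean AUC",
                               "SD AUC (folds)"))
  for (wn in names(report$widths)) {
    for (m in c("plann", "survival")) {
      col <- vapply(metrics, function(mm) report$widths[[wn]]$models[[m]][[mm]],
                    numeric(1))
      out[[paste0(m, "_", report$widths[[wn]]$width, "y")]] <- col
    }
  }
  out
}

#' Threshold/confusion table of an evaluation report
#'
#' Mean accuracy, specificity, sensitivity and PPV across intervals and
#' folds, per model, interval width and threshold (grid plus the
#' per-interval Youden-optimal threshold).
#'
#' @param report An [run_experiment()] result.
#' @return A long-format `data.frame`.
#' @export
threshold_table <- function(report) {
  do.call(rbind, lapply(names(report$widths), function(wn) {
    do.call(rbind, lapply(c("plann", "survival"), function(m) {
      cf <- report$widths[[wn]]$models[[m]]$confusion
      data.frame(width = report$widths[[wn]]$width, model = m, cf,
                 row.names = NULL)
    }))
  }))
}

#' Write an evaluation report to disk
#'
#' JSON for the full report plus two CSVs shaped like the headline
#' performance and threshold tables.
#'
#' @param report An [run_experiment()] result.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  perf <- performance_table(report)
  thr <- threshold_table(report)
  jsonlite::write_json(list(
    descriptives = report$descriptives,
    performance = perf, thresholds = thr,
    config = unclass(report$config)[c("widths", "folds", "seed", "min_age",
                                      "brier_ages", "thresholds",
                                      "brier_weighting", "glm_ridge")]
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", force = TRUE)
  utils::write.csv(perf, file.path(dir, "performance.csv"), row.names = FALSE)
  utils::write.csv(thr, file.path(dir, "thresholds.csv"), row.names = FALSE)
  invisible(file.path(dir, c("report.json", "performance.csv", "thresholds.csv")))
}

#' Select exemplar individuals from a test fold
#'
#' The subject with the earliest diagnosis age is the "earlier-onset"
#' exemplar, the subject with the median diagnosis age (lower-middle
#' element for even counts) the "mid-onset" exemplar, and the subject with
#' the longest censoring time the "no-onset" exemplar; their predicted
#' survival curves are returned for plotting.
#'
#' @param preds A [prediction_set()] for the test fold.
#' @return List of class `"exemplars"` with `earlier_onset`, `mid_onset`,
#'   `no_onset` (each: `id`, `outcome_age`, `survival`, and the scheme) and
#'   `same_subject = TRUE` when a single event subject fills both onset
#'   roles.
#' @export
select_exemplars <- function(preds) {
  ev <- which(preds$event == 1)
  cs <- which(preds$event == 0)
  if (!length(ev)) stop("test fold contains no event subjects", call. = FALSE)
  if (!length(cs)) stop("test fold contains no censored subjects", call. = FALSE)
  pick <- function(i) list(id = preds$ids[i], outcome_age = preds$outcome_age[i],
                           survival = preds$survival[i, ])
  t_ev <- preds$outcome_age[ev]
  earlier <- ev[which.min(t_ev)]
  mid <- ev[order(t_ev)][floor((length(ev) + 1) / 2)]
  noon <- cs[which.max(preds$outcome_age[cs])]
  structure(list(earlier_onset = pick(earlier), mid_onset = pick(mid),
                 no_onset = pick(noon), scheme = preds$scheme,
                 same_subject = earlier == mid),
            class = "exemplars")
}

#' Plot exemplar survival curves
#'
#' Step curves of predicted event-free probability against age for the
#' three exemplar individuals.
#'
#' @param x An [select_exemplars()] result.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of curves.
#' @export
plot.exemplars <- function(x, ...) {
  b <- x$scheme$boundaries
  curves <- cbind(x$earlier_onset$survival, x$mid_onset$survival,
                  x$no_onset$survival)
  graphics::matplot(b, rbind(1, curves), type = "s", lty = 1, lwd = 2,
                    col = c("#1f77b4", "#ff7f0e", "#2ca02c"),
                    xlab = "Age (years)", ylab = "Predicted survival",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomleft", bty = "n",
                   legend = sprintf("%s (%.2f y)",
                                    c("earlier-onset", "mid-onset", "no-onset"),
                                    c(x$earlier_onset$outcome_age,
                                      x$mid_onset$outcome_age,
                                      x$no_onset$outcome_age)),
                   col = c("#1f77b4", "#ff7f0e", "#2ca02c"), lwd = 2)
  invisible(curves)
}

#' Cohort descriptive table
#'
#' Counts with percentages and Wald confidence intervals for the binary
#' covariates, and means with confidence intervals for the continuous
#' ones, for the full cohort and for the subjects who experienced the
#' outcome. Time-varying indicators are summarized as "ever experienced
#' before the outcome or censoring"; episode counts as the cumulative
#' antecedent count at the outcome.
#'
#' @param cohort A [cohort()].
#' @return A `data.frame` with columns `variable`, `type`, and per group
#'   (`all`, `events`): `n` (count or mean), `pct_or_mean`, `ci_lower`,
#'   `ci_upper`.
#' @export
descriptive_table <- function(cohort) {
  groups <- list(all = cohort,
                 events = cohort(unclass(cohort)[cohort_events(cohort) == 1]))
  summarize_group <- function(co) {
    n <- length(co)
    ev_before <- function(f) vapply(co, f, numeric(1))
    bin_row <- function(variable, x) {
      ci <- ci_proportion(sum(x), n)
      data.frame(variable = variable, type = "binary", n = sum(x),
                 pct_or_mean = 100 * mean(x), ci_lower = ci[1], ci_upper = ci[2])
    }
    num_row <- function(variable, x) {
      ci <- ci_mean(mean(x), stats::sd(x), n)
      data.frame(variable = variable, type = "mean", n = n,
                 pct_or_mean = mean(x), ci_lower = ci[1], ci_upper = ci[2])
    }
    ind_rows <- do.call(rbind, lapply(mood_indicators(), function(nm)
      bin_row(nm, ev_before(function(s) {
        a <- s$onset_ages[nm]
        as.numeric(length(a) == 1 && !is.na(a) && a < s$outcome_age)
      }))))
    rbind(
      bin_row("sex_male", ev_before(function(s) s$sex_male)),
      num_row("age_at_outcome_or_censoring", ev_before(function(s) s$outcome_age)),
      bin_row("parental_lithium_response",
              ev_before(function(s) s$parental_lithium_response)),
      num_row("parental_onset_age", ev_before(function(s) s$parental_onset_age)),
      bin_row("abuse_yes", ev_before(function(s) as.numeric(s$abuse == "yes"))),
      bin_row("abuse_missing",
              ev_before(function(s) as.numeric(s$abuse == "missing"))),
      ind_rows,
      num_row("major_episodes", ev_before(function(s)
        sum(s$major_episode_ages < s$outcome_age))),
      num_row("minor_episodes", ev_before(function(s)
        sum(s$minor_episode_ages < s$outcome_age))))
  }
  a <- summarize_group(groups$all)
  e <- summarize_group(groups$events)
  names(e)[3:6] <- paste0("events_", names(e)[3:6])
  cbind(a, e[, 3:6])
}
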