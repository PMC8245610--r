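# Censoring-aware evaluation of discrete-hazard predictions.
#
# All metrics operate on a `prediction_set`: per test subject, the
# predicted hazard per interval, the implied step survival curve, and the
# observed outcome (age and event flag). Undefined quantities (empty risk
# sets, no predicted positives) are raised/flagged explicitly — never
# silently imputed as 0 — so aggregation layers can exclude and count them.

#' Bundle predictions with observed outcomes
#'
#' @param scheme The [interval_scheme()] the predictions live on.
#' @param ids Character vector of subject ids.
#' @param outcome_age Observed age at diagnosis or censoring, per subject.
#' @param event 0/1 event flags.
#' @param hazard Matrix (subjects x intervals) of predicted conditional
#'   hazards over the whole scheme.
#' @return An object of class `"prediction_set"` with the above plus
#'   `survival`, the row-wise product-limit survival matrix.
#' @export
prediction_set <- function(scheme, ids, outcome_age, event, hazard) {
  hazard <- as.matrix(hazard)
  stopifnot(length(ids) == nrow(hazard), length(outcome_age) == nrow(hazard),
            length(event) == nrow(hazard), ncol(hazard) == scheme$n_intervals)
  if (any(hazard < 0 | hazard > 1))
    stop("hazards must lie in [0, 1]", call. = FALSE)
  surv <- t(apply(hazard, 1, survival_from_hazards))
  if (scheme$n_intervals == 1) surv <- matrix(surv, ncol = 1)
  structure(list(scheme = scheme, ids = as.character(ids),
                 outcome_age = outcome_age, event = event,
                 hazard = hazard, survival = surv),
            class = "prediction_set")
}

#' Predict whole-horizon survival curves for a cohort
#'
#' Builds covariate rows for every interval of the scheme (time-varying
#' covariates follow the lag convention and freeze at their last
#' pre-outcome value), predicts conditional hazards with the supplied
#' model, and composes survival curves.
#'
#' @param model A `"hazard_glm"` or `"plann"` fit (anything with a
#'   `predict` method mapping person-period rows to hazards).
#' @param cohort A [cohort()] of (test) subjects.
#' @param scheme An [interval_scheme()] matching the model.
#' @return A [prediction_set()].
#' @export
predict_survival_curves <- function(model, cohort, scheme) {
  rows <- do.call(rbind, c(lapply(cohort, prediction_rows, scheme = scheme),
                           make.row.names = FALSE))
  h <- if (inherits(model, "hazard_glm")) predict(model, rows, fill = "carry")
  else predict(model, rows)
  hz <- matrix(h, nrow = length(cohort), ncol = scheme$n_intervals, byrow = TRUE)
  prediction_set(scheme, names(cohort), cohort_times(cohort),
                 cohort_events(cohort), hz)
}

undefined_metric <- function(msg) {
  stop(errorCondition(msg, class = c("plannsurv_undefined_metric",
                                     "error", "condition")))
}

#' Time-dependent concordance index
#'
#' Over comparable pairs — i with an observed event at t_i, j with observed
#' time strictly greater than t_i — counts the pairs in which the predicted
#' survival at t_i is lower for the subject who failed, with ties in
#' predicted survival credited 1/2. A value of 0.5 is chance level.
#' Predicted survival at t_i is taken through the interval containing t_i
#' (within-interval ordering is not resolvable in discrete time, so the
#' interval's own hazard participates in the comparison).
#'
#' @param preds A [prediction_set()].
#' @return Concordant fraction in \[0, 1\].
#' @export
td_c_index <- function(preds) {
  n <- length(preds$ids)
  if (n < 2) undefined_metric("need at least two subjects")
  num <- 0
  den <- 0
  for (i in which(preds$event == 1)) {
    ti <- preds$outcome_age[i]
    js <- which(preds$outcome_age > ti)
    if (!length(js)) next
    si <- survival_through_interval(preds$scheme, preds$survival[i, ], ti)
    sj <- vapply(js, function(j)
      survival_through_interval(preds$scheme, preds$survival[j, ], ti),
      numeric(1))
    num <- num + sum(si < sj) + 0.5 * sum(si == sj)
    den <- den + length(js)
  }
  if (den == 0) undefined_metric("no comparable pairs for the c-index")
  num / den
}

#' Kaplan-Meier estimate of the censoring survivor function
#'
#' Estimates G(t) = P(C > t), the survivor function of the censoring (last
#' follow-up visit) distribution, by Kaplan-Meier with the roles of event
#' and censoring reversed. Used for the IPCW weights of [brier_score()];
#' in a cross-validated pipeline G is estimated on the training folds and
#' supplied to the test-fold evaluation.
#'
#' @param times Observed outcome ages.
#' @param events 0/1 event flags (1 = diagnosed; 0 = censored).
#' @return A function `G(t, left = FALSE)`; `left = TRUE` gives the left
#'   limit G(t-).
#' @export
censoring_km <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  jump_t <- fit$time[fit$n.event > 0]
  jump_s <- fit$surv[fit$n.event > 0]
  function(t, left = FALSE) {
    vapply(t, function(tt) {
      keep <- if (left) jump_t < tt else jump_t <= tt
      if (!any(keep)) 1 else jump_s[max(which(keep))]
    }, numeric(1))
  }
}

#' Brier score at a fixed age
#'
#' Mean squared difference between the predicted event-free probability at
#' `at_age` and the observed event-free status. Under `"ipcw"` weighting,
#' contributions are inverse-weighted by the Kaplan-Meier censoring
#' survivor function G: events before `at_age` by `1/G(t_i-)`, subjects
#' still under observation by `1/G(at_age)`; subjects censored before
#' `at_age` carry zero weight. 0.25 for a constant-0.5 prediction with no
#' censoring is the chance level.
#'
#' @param preds A [prediction_set()].
#' @param at_age Evaluation age in years (within the scheme's range).
#' @param weighting `"ipcw"` (default) or `"unweighted"` (zero weight for
#'   subjects whose status at `at_age` is unknown, no reweighting of the
#'   rest).
#' @param G Optional censoring survivor function (as returned by the
#'   internal Kaplan-Meier estimator), e.g. estimated on training folds;
#'   defaults to estimating G from `preds` itself.
#' @return The (weighted) Brier score.
#' @export
brier_score <- function(preds, at_age, weighting = c("ipcw", "unweighted"),
                        G = NULL) {
  weighting <- match.arg(weighting)
  if (at_age < preds$scheme$min_age || at_age > max(preds$scheme$boundaries))
    stop("'at_age' lies outside the interval scheme", call. = FALSE)
  n <- length(preds$ids)
  s_hat <- vapply(seq_len(n), function(i)
    survival_at_age(preds$scheme, preds$survival[i, ], at_age), numeric(1))
  t_obs <- preds$outcome_age
  ev <- preds$event
  known_event <- ev == 1 & t_obs <= at_age
  still_free <- t_obs > at_age
  w <- numeric(n)
  if (weighting == "ipcw") {
    if (is.null(G)) G <- censoring_km(t_obs, ev)
    if (any(known_event)) {
      g <- G(t_obs[known_event], left = TRUE)
      if (any(g <= 0))
        stop("censoring survivor estimate is 0 before age ", at_age,
             "; IPCW weights undefined", call. = FALSE)
      w[known_event] <- 1 / g
    }
    if (any(still_free)) {
      ga <- G(at_age)
      if (ga <= 0)
        stop("censoring survivor estimate is 0 at age ", at_age,
             "; IPCW weights undefined", call. = FALSE)
      w[still_free] <- 1 / ga
    }
    denom <- n
  } else {
    w[known_event | still_free] <- 1
    denom <- sum(w)
    if (denom == 0) undefined_metric("no subject has known status at this age")
  }
  err <- (as.numeric(still_free) - s_hat)^2
  sum(w * err) / denom
}

#' Mean Brier score over a set of ages
#'
#' Arithmetic mean of [brier_score()] at each age; the default ages 15, 20
#' and 25 years summarize calibration across adolescence and early
#' adulthood.
#'
#' @inheritParams brier_score
#' @param ages Numeric vector of evaluation ages (default `c(15, 20, 25)`).
#' @return Mean Brier score.
#' @export
mean_brier <- function(preds, ages = c(15, 20, 25),
                       weighting = c("ipcw", "unweighted"), G = NULL) {
  weighting <- match.arg(weighting)
  mean(vapply(ages, function(a) brier_score(preds, a, weighting, G), numeric(1)))
}

# risk set for interval k: at risk at the interval start and not censored
# within it. Returns indices of cases (event in k) and controls (survived k).
interval_risk_set <- function(preds, k) {
  lo <- interval_start(preds$scheme, k)
  hi <- interval_end(preds$scheme, k)
  t_obs <- preds$outcome_age
  ev <- preds$event
  cases <- which(ev == 1 & t_obs >= lo & t_obs < hi)
  controls <- which(t_obs >= hi - 1e-9)
  list(cases = cases, controls = controls)
}

#' Per-interval AUC of the predicted hazard
#'
#' Among subjects at risk at the start of interval k (excluding those
#' censored within it), the rank-sum AUC of the predicted hazard for k as a
#' classifier of event-in-k versus survived-k; ties credited 1/2.
#'
#' @param preds A [prediction_set()].
#' @param k Interval index.
#' @return AUC in \[0, 1\]. Degenerate risk sets (no events or no
#'   survivors) raise an error of class `"plannsurv_undefined_metric"`.
#' @export
interval_auc <- function(preds, k) {
  rs <- interval_risk_set(preds, k)
  n1 <- length(rs$cases)
  n0 <- length(rs$controls)
  if (n1 == 0 || n0 == 0)
    undefined_metric(sprintf("interval %d risk set has %d events / %d survivors",
                             k, n1, n0))
  h <- preds$hazard[c(rs$cases, rs$controls), k]
  r <- rank(h)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion metrics at a hazard threshold
#'
#' Classifies the interval-k risk set as predicted-positive when the
#' predicted hazard is `>= threshold` and reports the standard 2x2 rates.
#' When no subject is predicted positive, PPV is undefined and returned as
#' `NA` with `n_predicted_positive = 0` — not silently zero.
#'
#' @inheritParams interval_auc
#' @param threshold Probability threshold in \[0, 1\].
#' @return List with `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `n_predicted_positive`, `n_cases`, `n_controls`.
#' @export
confusion_at_threshold <- function(preds, k, threshold) {
  if (threshold < 0 || threshold > 1)
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  rs <- interval_risk_set(preds, k)
  n1 <- length(rs$cases)
  n0 <- length(rs$controls)
  if (n1 == 0 || n0 == 0)
    undefined_metric(sprintf("interval %d risk set has %d events / %d survivors",
                             k, n1, n0))
  hc <- preds$hazard[rs$cases, k]
  hn <- preds$hazard[rs$controls, k]
  tp <- sum(hc >= threshold); fn <- n1 - tp
  fp <- sum(hn >= threshold); tn <- n0 - fp
  list(accuracy = (tp + tn) / (n1 + n0),
       sensitivity = tp / n1,
       specificity = tn / n0,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       n_predicted_positive = tp + fp, n_cases = n1, n_controls = n0)
}

#' Youden-optimal hazard threshold for an interval
#'
#' Scans the observed predicted hazards of the interval-k risk set and
#' returns the cut maximizing Youden's J = sensitivity + specificity - 1
#' (classification at `hazard >= cut`); ties break toward the smaller cut.
#' The returned threshold is the midpoint between the chosen cut and the
#' next-smaller observed value when one exists. When every hazard is tied,
#' J = 0 everywhere: the smallest candidate is returned with attribute
#' `degenerate = TRUE`.
#'
#' @inheritParams interval_auc
#' @return The threshold (numeric scalar), with attribute `youden_j`.
#' @export
optimal_threshold <- function(preds, k) {
  rs <- interval_risk_set(preds, k)
  n1 <- length(rs$cases)
  n0 <- length(rs$controls)
  if (n1 == 0 || n0 == 0)
    undefined_metric(sprintf("interval %d risk set has %d events / %d survivors",
                             k, n1, n0))
  hc <- preds$hazard[rs$cases, k]
  hn <- preds$hazard[rs$controls, k]
  cand <- sort(unique(c(hc, hn)))
  j <- vapply(cand, function(cc)
    mean(hc >= cc) + mean(hn < cc) - 1, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]          # ties -> smaller cut
  cut <- cand[best]
  thr <- if (best > 1) (cand[best - 1] + cut) / 2 else cut
  structure(thr, youden_j = j[best],
            degenerate = length(cand) == 1)
}

#' Stratified cross-validation folds
#'
#' Partitions a cohort into k disjoint folds with event and non-event
#' subjects dealt round-robin after a seeded shuffle, so fold event counts
#' differ by at most one.
#'
#' @param cohort A [cohort()].
#' @param k Number of folds (>= 2, <= cohort size).
#' @param seed Integer seed; the assignment is reproducible.
#' @return Named integer vector of fold ids (1..k), one per subject.
#' @export
stratified_folds <- function(cohort, k = 10, seed = 1) {
  n <- length(cohort)
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  if (k > n) stop("more folds than subjects", call. = FALSE)
  ev <- cohort_events(cohort)
  fold <- integer(n)
  with_seed(seed, {
    for (g in c(1, 0)) {
      idx <- which(ev == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  stats::setNames(fold, names(cohort))
}

#' Wald confidence interval for a percentage
#'
#' The large-sample interval `100 * (p +/- 1.96 * sqrt(p * (1 - p) / n))`
#' for an observed proportion, reported in percent. The formula is applied
#' literally; set `clip = TRUE` to truncate to \[0, 100\].
#'
#' @param count Number of successes (0..n).
#' @param n Sample size (>= 1).
#' @param clip Truncate the interval to \[0, 100\]?
#' @return Numeric `c(lower, upper)` in percent.
#' @export
#' @examples
#' round(ci_proportion(121, 292), 1)  # 35.8 47.1
ci_proportion <- function(count, n, clip = FALSE) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (count < 0 || count > n) stop("'count' must lie in 0..n", call. = FALSE)
  p <- count / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  out <- 100 * c(lower = p - half, upper = p + half)
  if (clip) out <- pmin(pmax(out, 0), 100)
  out
}

#' Wald confidence interval for a mean
#'
#' `m +/- 1.96 * sd / sqrt(n)`, returned unrounded.
#'
#' @param m Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Sample size (>= 1).
#' @return Numeric `c(lower, upper)`.
#' @export
ci_mean <- function(m, sd, n) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  half <- 1.96 * sd / sqrt(n)
  c(lower = m - half, upper = m + half)
}
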