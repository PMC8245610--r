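# Builders and independent brute-force oracles. Everything here is written
# naively (explicit loops, no shared code with the package internals) so
# the fast implementations can be checked against it.

quick_subject <- function(id, outcome_age, event, sex = 0, onsets = numeric(0),
                          major = numeric(0), minor = numeric(0),
                          abuse = "no", lithium = 0, poa = 25) {
  subject(id, sex, lithium, poa, abuse, outcome_age, event,
          onset_ages = onsets, major_episode_ages = major,
          minor_episode_ages = minor)
}

# random prediction set for oracle comparisons (n <= 20); ties are forced
# in half the draws by rounding hazards to one decimal
random_prediction_set <- function(n = NULL, with_ties = NULL) {
  if (is.null(n)) n <- sample(4:20, 1)
  if (is.null(with_ties)) with_ties <- runif(1) < 0.5
  width <- sample(c(1, 3, 5), 1)
  scheme <- interval_scheme(width, 5, 25)
  t_obs <- runif(n, 5.5, 24.5)
  ev <- rbinom(n, 1, 0.6)
  hz <- matrix(runif(n * scheme$n_intervals, 0.01, 0.6), n)
  if (with_ties) hz <- round(hz, 1)
  prediction_set(scheme, paste0("s", seq_len(n)), t_obs, ev, hz)
}

# step survival evaluated naively at an age (completed intervals only)
oracle_surv_at <- function(preds, i, age) {
  s <- 1
  b <- preds$scheme$boundaries
  for (k in seq_len(preds$scheme$n_intervals)) {
    if (b[k + 1] <= age + 1e-9) s <- s * (1 - preds$hazard[i, k])
  }
  s
}

# survival through the interval containing the age (for ranking at event
# times): multiply (1-h) over every interval whose start is <= age
oracle_surv_through <- function(preds, i, age) {
  s <- 1
  b <- preds$scheme$boundaries
  any_k <- FALSE
  for (k in seq_len(preds$scheme$n_intervals)) {
    if (b[k] <= age + 1e-9) { s <- s * (1 - preds$hazard[i, k]); any_k <- TRUE }
  }
  if (!any_k) s <- 1 - preds$hazard[i, 1]
  s
}

# exhaustive O(n^2) pairwise time-dependent concordance
oracle_cindex <- function(preds) {
  num <- 0; den <- 0
  n <- length(preds$ids)
  for (i in seq_len(n)) {
    if (preds$event[i] != 1) next
    ti <- preds$outcome_age[i]
    for (j in seq_len(n)) {
      if (preds$outcome_age[j] <= ti) next
      den <- den + 1
      si <- oracle_surv_through(preds, i, ti)
      sj <- oracle_surv_through(preds, j, ti)
      if (si < sj) num <- num + 1
      else if (si == sj) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# hand-rolled Kaplan-Meier of the censoring distribution, G(t) = P(C > t)
oracle_G <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; cens <- 1 - events[ord]
  ut <- sort(unique(times))
  surv <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (tt in ut) {
    at_risk <- sum(times >= tt)
    d <- sum(cens == 1 & times == tt)
    if (d > 0) {
      surv <- surv * (1 - d / at_risk)
      out_t <- c(out_t, tt); out_s <- c(out_s, surv)
    }
  }
  function(t, left = FALSE) {
    sel <- if (left) out_t < t else out_t <= t
    if (!any(sel)) 1 else out_s[max(which(sel))]
  }
}

oracle_brier <- function(preds, at_age, weighting = "ipcw") {
  n <- length(preds$ids)
  G <- oracle_G(preds$outcome_age, preds$event)
  tot <- 0; denom <- if (weighting == "ipcw") n else 0
  for (i in seq_len(n)) {
    ti <- preds$outcome_age[i]; ei <- preds$event[i]
    s <- oracle_surv_at(preds, i, at_age)
    if (ei == 1 && ti <= at_age) {
      w <- if (weighting == "ipcw") 1 / G(ti, left = TRUE) else 1
      tot <- tot + w * (0 - s)^2
      if (weighting != "ipcw") denom <- denom + 1
    } else if (ti > at_age) {
      w <- if (weighting == "ipcw") 1 / G(at_age) else 1
      tot <- tot + w * (1 - s)^2
      if (weighting != "ipcw") denom <- denom + 1
    }
  }
  tot / denom
}

# exhaustive pair-count AUC for interval k
oracle_interval_auc <- function(preds, k) {
  lo <- preds$scheme$boundaries[k]; hi <- preds$scheme$boundaries[k + 1]
  cases <- which(preds$event == 1 & preds$outcome_age >= lo &
                   preds$outcome_age < hi)
  ctrl <- which(preds$outcome_age >= hi - 1e-9)
  if (!length(cases) || !length(ctrl)) return(NA_real_)
  num <- 0
  for (i in cases) for (j in ctrl) {
    if (preds$hazard[i, k] > preds$hazard[j, k]) num <- num + 1
    else if (preds$hazard[i, k] == preds$hazard[j, k]) num <- num + 0.5
  }
  num / (length(cases) * length(ctrl))
}

# exhaustive scan over all candidate cuts for the Youden threshold
oracle_optimal_threshold <- function(preds, k) {
  lo <- preds$scheme$boundaries[k]; hi <- preds$scheme$boundaries[k + 1]
  cases <- which(preds$event == 1 & preds$outcome_age >= lo &
                   preds$outcome_age < hi)
  ctrl <- which(preds$outcome_age >= hi - 1e-9)
  if (!length(cases) || !length(ctrl)) return(NA_real_)
  hc <- preds$hazard[cases, k]; hn <- preds$hazard[ctrl, k]
  cand <- sort(unique(c(hc, hn)))
  best_j <- -Inf; best_i <- NA
  for (i in seq_along(cand)) {
    jj <- mean(hc >= cand[i]) + mean(hn < cand[i]) - 1
    if (jj > best_j + 1e-12) { best_j <- jj; best_i <- i }
  }
  if (best_i > 1) (cand[best_i - 1] + cand[best_i]) / 2 else cand[best_i]
}

# derivative-free minimization with restarts until the improvement stalls
nm_minimize <- function(par, fn) {
  best <- optim(par, fn, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-13))
  for (r in 1:25) {
    nxt <- optim(best$par, fn, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-13))
    if (best$value - nxt$value < 1e-10) { best <- nxt; break }
    best <- nxt
  }
  best
}

# naive double-loop forward pass through a one-hidden-layer sigmoid net
oracle_forward <- function(W1, b1, W2, b2, X) {
  n <- nrow(X); h <- length(b1)
  out <- numeric(n)
  sig <- function(z) 1 / (1 + exp(-z))
  for (i in seq_len(n)) {
    acc <- b2
    for (j in seq_len(h)) {
      z <- b1[j]
      for (p in seq_len(ncol(X))) z <- z + X[i, p] * W1[p, j]
      acc <- acc + sig(z) * W2[j]
    }
    out[i] <- sig(acc)
  }
  out
}

# small random cohort + single-width person-period table for GLM checks;
# redraws until every interval and covariate stratum has both outcomes, so
# the unpenalized MLE is finite and comparable with reference optimizers
random_small_table <- function(n = 15, width = 5) {
  scheme <- interval_scheme(width, 5, 25)
  for (try in 1:1000) {
    subs <- lapply(seq_len(n), function(i) {
      ev <- rbinom(1, 1, 0.6)
      # censored subjects may outlive the scheme so late intervals also
      # contain non-event rows
      t_obs <- if (ev == 1) runif(1, 6, 24.5) else runif(1, 6, 29)
      quick_subject(paste0("r", i), t_obs, ev,
                    sex = rbinom(1, 1, 0.5),
                    onsets = if (runif(1) < 0.5) c(anxiety = runif(1, 5, 20)) else numeric(0))
    })
    pp <- expand_person_periods(cohort(subs), scheme)
    if (nrow(pp) == 0) next
    per_int <- tapply(pp$event_in_interval, pp$interval_index,
                      function(y) length(y) > 1 && any(y == 1) && any(y == 0))
    mixed <- function(x) {
      for (v in unique(x)) {
        y <- pp$event_in_interval[x == v]
        if (all(y == 1) || all(y == 0)) return(FALSE)
      }
      TRUE
    }
    if (!(all(unlist(per_int)) && mixed(pp$sex_male) && mixed(pp$anxiety)))
      next
    # reject jointly separated tables: the unpenalized MLE must be finite
    ref <- suppressWarnings(
      glm(event_in_interval ~ 0 + factor(interval_index) + sex_male + anxiety,
          family = binomial(), data = pp))
    if (ref$converged && max(abs(coef(ref))) < 8) return(pp)
  }
  stop("could not draw a well-conditioned table")
}
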