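perfect_preds <- function() {
  # three events at 7, 12, 17 plus one long censored subject; hazard order
  # matches event order exactly
  sc <- interval_scheme(5, 5, 25)
  hz <- rbind(c(0.9, 0.9, 0.9, 0.9),
              c(0.5, 0.5, 0.5, 0.5),
              c(0.2, 0.2, 0.2, 0.2),
              c(0.01, 0.01, 0.01, 0.01))
  prediction_set(sc, paste0("s", 1:4), c(7, 12, 17, 24), c(1, 1, 1, 0), hz)
}

test_that("the time-dependent c-index is 1 for perfect ranking and 0.5 for ties", {
  expect_equal(td_c_index(perfect_preds()), 1)
  sc <- interval_scheme(5, 5, 25)
  tied <- prediction_set(sc, paste0("s", 1:4), c(7, 12, 17, 24), c(1, 1, 1, 0),
                         matrix(0.3, 4, 4))
  expect_equal(td_c_index(tied), 0.5)
  # no comparable pairs: single event at the latest time
  none <- prediction_set(sc, c("a", "b"), c(24, 7), c(0, 1),
                         matrix(0.3, 2, 4))
  expect_equal(td_c_index(none), 0.5)  # b fails first, a survives: comparable
  solo <- prediction_set(sc, c("a", "b"), c(7, 7), c(1, 1), matrix(0.3, 2, 4))
  expect_error(td_c_index(solo), class = "plannsurv_undefined_metric")
})

test_that("c-index and interval AUC match exhaustive pair enumeration", {
  set.seed(101)
  for (rep in 1:30) {
    ps <- random_prediction_set()
    oc <- oracle_cindex(ps)
    if (is.na(oc)) {
      expect_error(td_c_index(ps), class = "plannsurv_undefined_metric")
    } else {
      expect_equal(td_c_index(ps), oc)
    }
    for (k in c(1, ps$scheme$n_intervals)) {
      oa <- oracle_interval_auc(ps, k)
      if (is.na(oa)) {
        expect_error(interval_auc(ps, k), class = "plannsurv_undefined_metric")
      } else {
        expect_equal(interval_auc(ps, k), oa)
      }
    }
  }
})

test_that("rank metrics are invariant under strictly monotone transforms", {
  set.seed(102)
  ps <- random_prediction_set(n = 15, with_ties = FALSE)
  trans <- prediction_set(ps$scheme, ps$ids, ps$outcome_age, ps$event,
                          ps$hazard^3)
  k <- which(!is.na(vapply(seq_len(ps$scheme$n_intervals), function(k)
    oracle_interval_auc(ps, k), numeric(1))))[1]
  expect_equal(interval_auc(ps, k), interval_auc(trans, k))
  # survival curves under cubed hazards are a different monotone distortion
  # per subject, so the c-index needs its own single-interval check
  sc1 <- interval_scheme(20, 5, 25)
  hz <- matrix(runif(8), 8, 1)
  p1 <- prediction_set(sc1, paste0("s", 1:8), runif(8, 5.5, 24), rbinom(8, 1, 0.7), hz)
  p2 <- prediction_set(sc1, p1$ids, p1$outcome_age, p1$event, hz^3)
  expect_equal(td_c_index(p1), td_c_index(p2))
})

test_that("Brier score reproduces hand-computed values and chance level", {
  # perfect predictions, no censoring -> 0
  sc <- interval_scheme(5, 5, 25)
  perf <- prediction_set(sc, c("a", "b"), c(7, 24.9), c(1, 1),
                         rbind(c(1, 1, 1, 1), c(0, 0, 0, 0.999999)))
  expect_equal(brier_score(perf, 15, "unweighted"), 0)
  # constant 0.5 survival, no censoring -> exactly 0.25
  half <- prediction_set(sc, paste0("s", 1:6), c(7, 8, 12, 24, 24, 24),
                         rep(1, 6),
                         matrix(rep(c(0.5, 0, 0, 0), each = 6), 6))
  expect_equal(brier_score(half, 15, "unweighted"), 0.25)
  expect_equal(brier_score(half, 15, "ipcw"), 0.25)  # no censoring: identical
})

test_that("the IPCW Brier score matches a hand-computed weight table", {
  sc <- interval_scheme(5, 5, 25)
  hz <- rbind(c(0.30, 0.20, 0.1, 0.1),   # event 8
              c(0.20, 0.20, 0.1, 0.1),   # event 12
              c(0.10, 0.30, 0.1, 0.1),   # censored 10 -> zero weight
              c(0.10, 0.10, 0.1, 0.1),   # event 20
              c(0.05, 0.10, 0.1, 0.1),   # censored 22
              c(0.20, 0.10, 0.1, 0.1))   # censored 18
  ps <- prediction_set(sc, paste0("s", 1:6), c(8, 12, 10, 20, 22, 18),
                       c(1, 1, 0, 1, 0, 0), hz)
  # G jumps at censorings: G=0.8 on [10,18), 0.5333.. on [18,22), 0 after.
  # Weights at age 15: events 8, 12 -> 1/G(t-) = 1, 1.25;
  # subjects beyond 15 -> 1/G(15) = 1.25; censored-at-10 -> 0.
  expected <- (1 * 0.56^2 + 1.25 * 0.64^2 +
                 1.25 * ((1 - 0.81)^2 + (1 - 0.855)^2 + (1 - 0.72)^2)) / 6
  expect_equal(brier_score(ps, 15, "ipcw"), expected, tolerance = 1e-12)
  expect_equal(brier_score(ps, 15, "ipcw"), oracle_brier(ps, 15, "ipcw"),
               tolerance = 1e-12)
  # a training-fold G that hits 0 before the evaluation age is refused
  G0 <- censoring_km(c(8, 20), c(1, 0))
  expect_error(brier_score(ps, 21, "ipcw", G = G0), "0")
})

test_that("Brier scores match the independent oracle on random sets", {
  set.seed(103)
  for (rep in 1:20) {
    ps <- random_prediction_set()
    for (w in c("ipcw", "unweighted")) {
      age <- runif(1, 6, 0.8 * max(ps$outcome_age))
      skip <- w == "ipcw" &&
        any(ps$event == 0) && max(ps$outcome_age[ps$event == 0]) <= age
      if (!skip)
        expect_equal(brier_score(ps, age, w), oracle_brier(ps, age, w),
                     tolerance = 1e-12)
    }
  }
})

test_that("mean Brier is the arithmetic mean across evaluation ages", {
  sc <- interval_scheme(5, 5, 30)
  ps <- prediction_set(sc, paste0("s", 1:5), c(7, 12, 26, 27, 28),
                       c(1, 1, 0, 0, 0),
                       matrix(runif(25, 0.05, 0.3), 5))
  b <- vapply(c(15, 20, 25), function(a) brier_score(ps, a, "unweighted"),
              numeric(1))
  expect_equal(mean_brier(ps, weighting = "unweighted"), mean(b))
})

test_that("confusion metrics follow the 2x2 definitions and flag empty positives", {
  sc <- interval_scheme(5, 5, 10)
  hz <- matrix(c(0.6, 0.7, 0.8, 0.3,            # cases
                 0.6, 0.9, 0.1, 0.2, 0.3, 0.4), # controls
               ncol = 1)
  ps <- prediction_set(sc, paste0("s", 1:10),
                       c(rep(7, 4), rep(10, 6)),
                       c(rep(1, 4), rep(0, 6)), hz)
  cm <- confusion_at_threshold(ps, 1, 0.5)      # TP 3 FP 2 FN 1 TN 4
  expect_equal(cm$accuracy, 0.7)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 2 / 3)
  expect_equal(cm$ppv, 0.6)
  cm0 <- confusion_at_threshold(ps, 1, 0)
  expect_equal(cm0$sensitivity, 1)
  expect_equal(cm0$specificity, 0)
  cm1 <- confusion_at_threshold(ps, 1, 1)
  expect_equal(cm1$sensitivity, 0)
  expect_equal(cm1$specificity, 1)
  expect_true(is.na(cm1$ppv))
  expect_equal(cm1$n_predicted_positive, 0)
  expect_error(confusion_at_threshold(ps, 1, 1.2), "threshold")
})

test_that("threshold sweeps are monotone in sensitivity and specificity", {
  set.seed(104)
  for (rep in 1:10) {
    ps <- random_prediction_set()
    k <- which(!is.na(vapply(seq_len(ps$scheme$n_intervals), function(k)
      oracle_interval_auc(ps, k), numeric(1))))
    if (!length(k)) next
    k <- k[1]
    grid <- seq(0, 1, by = 0.05)
    cms <- lapply(grid, function(th) confusion_at_threshold(ps, k, th))
    sens <- vapply(cms, `[[`, numeric(1), "sensitivity")
    spec <- vapply(cms, `[[`, numeric(1), "specificity")
    expect_true(all(diff(sens) <= 1e-12))
    expect_true(all(diff(spec) >= -1e-12))
  }
})

test_that("the Youden threshold matches an exhaustive scan and its conventions", {
  # perfectly separated hazards: midpoint between the groups
  sc <- interval_scheme(5, 5, 10)
  ps <- prediction_set(sc, paste0("s", 1:6), c(7, 7, 7, 10, 10, 10),
                       c(1, 1, 1, 0, 0, 0),
                       matrix(c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3), ncol = 1))
  th <- optimal_threshold(ps, 1)
  expect_equal(as.numeric(th), (0.3 + 0.7) / 2)
  expect_equal(attr(th, "youden_j"), 1)
  # all-tied hazards: J = 0 everywhere, smallest candidate, degeneracy flag
  tied <- prediction_set(sc, paste0("s", 1:4), c(7, 7, 10, 10),
                         c(1, 1, 0, 0), matrix(0.4, 4, 1))
  tt <- optimal_threshold(tied, 1)
  expect_equal(as.numeric(tt), 0.4)
  expect_true(attr(tt, "degenerate"))
  set.seed(105)
  for (rep in 1:20) {
    ps <- random_prediction_set()
    for (k in c(1, ps$scheme$n_intervals)) {
      oth <- oracle_optimal_threshold(ps, k)
      if (is.na(oth)) {
        expect_error(optimal_threshold(ps, k),
                     class = "plannsurv_undefined_metric")
      } else {
        expect_equal(as.numeric(optimal_threshold(ps, k)), oth)
      }
    }
  }
})

test_that("stratified folds balance events and are reproducible", {
  subs <- lapply(1:292, function(i)
    quick_subject(paste0("s", i), 20, as.numeric(i <= 112)))
  co <- cohort(subs)
  f1 <- stratified_folds(co, 10, seed = 17)
  f2 <- stratified_folds(co, 10, seed = 17)
  expect_identical(f1, f2)
  ev <- sapply(co, `[[`, "event")
  per_fold_events <- table(f1[ev == 1])
  expect_true(all(per_fold_events %in% c(11, 12)))
  expect_equal(sort(unique(f1)), 1:10)
  expect_equal(length(f1), 292)                 # a partition: every subject once
  expect_error(stratified_folds(co, 300, seed = 1), "folds")
  expect_error(stratified_folds(co, 1, seed = 1), "k")
})

test_that("Wald intervals follow the stated formulas", {
  expect_equal(round(ci_proportion(121, 292), 1), c(lower = 35.8, upper = 47.1))
  expect_equal(round(ci_proportion(129, 292), 1), c(lower = 38.5, upper = 49.9))
  expect_equal(ci_proportion(0, 100), c(lower = 0, upper = 0))
  expect_error(ci_proportion(5, 0), "n")
  expect_equal(ci_mean(10, 0, 25), c(lower = 10, upper = 10))
  expect_equal(ci_mean(0, 1, 4), c(lower = -0.98, upper = 0.98))
  set.seed(106)
  for (rep in 1:10) {
    m <- rnorm(1); s <- runif(1); n <- sample(2:50, 1)
    expect_equal(mean(ci_mean(m, s, n)), m)
  }
})
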