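test_that("interval schemes partition the age axis into half-open intervals", {
  sc <- interval_scheme(5, 5, 25)
  expect_equal(sc$boundaries, c(5, 10, 15, 20, 25))
  expect_equal(sc$n_intervals, 4)
  expect_equal(interval_scheme(1, 5, 8)$boundaries, 5:8)
  expect_equal(interval_scheme(3, 5, 11)$boundaries, c(5, 8, 11))
  # last interval may overshoot max_age
  expect_equal(interval_scheme(3, 5, 12)$boundaries, c(5, 8, 11, 14))
  expect_error(interval_scheme(0, 5, 25), "width")
  expect_error(interval_scheme(1, 10, 10), "max_age")
})

test_that("event subjects contribute rows through the event interval", {
  sc <- interval_scheme(1, 5, 40)
  s <- quick_subject("early", 11.64, 1)
  pp <- expand_person_periods(cohort(list(s)), sc)
  expect_equal(nrow(pp), 7)
  expect_equal(pp$interval_start, 5:11)
  expect_equal(pp$event_in_interval, c(rep(0, 6), 1))
})

test_that("censored subjects appear only in fully survived intervals", {
  sc <- interval_scheme(5, 5, 40)
  s <- quick_subject("cens", 39.79, 0)
  pp <- expand_person_periods(cohort(list(s)), sc)
  expect_equal(nrow(pp), 6)                 # [5,10) .. [30,35)
  expect_equal(max(pp$interval_end), 35)
  expect_true(all(pp$event_in_interval == 0))
})

test_that("expansion handles empty cohorts and rejects pre-enrolment outcomes", {
  sc <- interval_scheme(1, 5, 40)
  expect_equal(nrow(expand_person_periods(cohort(list()), sc)), 0)
  s <- quick_subject("bad", 3.2, 1)
  expect_error(expand_person_periods(cohort(list(s)), sc), "bad")
})

test_that("row counts match an independent per-subject enumeration", {
  set.seed(71)
  for (rep in 1:10) {
    width <- sample(c(1, 3, 5), 1)
    sc <- interval_scheme(width, 5, 30)
    subs <- lapply(1:12, function(i)
      quick_subject(paste0("s", i), runif(1, 5.5, 29.5), rbinom(1, 1, 0.5)))
    pp <- expand_person_periods(cohort(subs), sc)
    expected <- sum(vapply(subs, function(s) {
      if (s$event == 1) {
        # index of the interval containing the event age
        floor((s$outcome_age - 5) / width) + 1
      } else {
        # fully survived intervals only
        sum(5 + width * seq_len(sc$n_intervals) <= s$outcome_age)
      }
    }, numeric(1)))
    expect_equal(nrow(pp), expected)
  }
})

test_that("per subject at most one event row, in last position, matching the flag", {
  set.seed(72)
  sc <- interval_scheme(3, 5, 30)
  subs <- lapply(1:20, function(i)
    quick_subject(paste0("s", i), runif(1, 5.5, 29.5), rbinom(1, 1, 0.5)))
  pp <- expand_person_periods(cohort(subs), sc)
  for (s in subs) {
    rows <- pp[pp$subject_id == s$id, ]
    if (nrow(rows) == 0) next
    expect_lte(sum(rows$event_in_interval), 1)
    expect_equal(sum(rows$event_in_interval), s$event)
    if (s$event == 1)
      expect_equal(rows$event_in_interval[nrow(rows)], 1)
  }
})

test_that("indicator status is lagged one interval and antecedent-only", {
  sc <- interval_scheme(1, 5, 40)
  s <- quick_subject("lag", 30, 1, onsets = c(anxiety = 14.2))
  k_14 <- which(sc$boundaries == 14)       # interval [14,15)
  expect_equal(lagged_indicator(s, "anxiety", k_14, sc), 0)
  expect_equal(lagged_indicator(s, "anxiety", k_14 + 1, sc), 1)
  expect_equal(lagged_indicator(s, "anxiety", sc$n_intervals, sc), 1)
  # never-onset indicator is 0 everywhere
  for (k in seq_len(sc$n_intervals))
    expect_equal(lagged_indicator(s, "sleep", k, sc), 0)
  # onset after diagnosis is ignored entirely
  s2 <- quick_subject("post", 18, 1, onsets = c(anxiety = 20))
  for (k in seq_len(sc$n_intervals))
    expect_equal(lagged_indicator(s2, "anxiety", k, sc), 0)
  expect_error(lagged_indicator(s, "nonesuch", 1, sc), "unknown indicator")
})

test_that("cumulative episode counts respect the lag convention", {
  sc <- interval_scheme(1, 5, 40)
  s <- quick_subject("ep", 30, 1, major = c(12.5, 13.2, 15.5))
  k15 <- which(sc$boundaries == 15)        # interval [15,16)
  expect_equal(lagged_cumulative_episodes(s, "major", k15, sc), 2)
  expect_equal(lagged_cumulative_episodes(s, "major", k15 + 1, sc), 3)
  expect_equal(lagged_cumulative_episodes(s, "minor", k15, sc), 0)
})

test_that("perturbing information at or after an interval start never leaks into its row", {
  set.seed(73)
  sc <- interval_scheme(3, 5, 30)
  base <- quick_subject("leak", 26, 1, onsets = c(anxiety = 10),
                        major = c(9, 12))
  pp0 <- expand_person_periods(cohort(list(base)), sc)
  for (k in seq_len(max(pp0$interval_index))) {
    start <- pp0$interval_start[k]
    # move an onset / add episodes at or after this interval's start
    pert <- quick_subject("leak", 26, 1,
                          onsets = c(anxiety = 10, sleep = start + 0.1),
                          major = c(9, 12, start, start + 1))
    pp1 <- expand_person_periods(cohort(list(pert)), sc)
    cols <- pp_covariate_names()
    expect_equal(as.numeric(pp1[k, cols]), as.numeric(pp0[k, cols]))
  }
})

test_that("survival curves from hazards are product-limit, monotone and bounded", {
  expect_equal(survival_from_hazards(c(0.1, 0.2)), c(0.9, 0.72))
  expect_equal(survival_from_hazards(numeric(0)), numeric(0))
  expect_equal(survival_from_hazards(c(1, 0.3)), c(0, 0))
  expect_error(survival_from_hazards(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(74)
  for (i in 1:25) {
    s <- survival_from_hazards(runif(sample(1:30, 1)))
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("cohort round-trips through the CSV representation", {
  co <- cohort(list(
    quick_subject("a", 19.2, 1, sex = 1, onsets = c(anxiety = 12.5),
                  major = c(15, 16.2), abuse = "yes"),
    quick_subject("b", 30.4, 0, abuse = "missing", minor = 14.1)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(file.path(dir, "subjects.csv"),
                     file.path(dir, "onsets.csv"),
                     file.path(dir, "episodes.csv"))
  sc <- interval_scheme(1, 5, 35)
  expect_equal(expand_person_periods(co2, sc), expand_person_periods(co, sc))
})
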