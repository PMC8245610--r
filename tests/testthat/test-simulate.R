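test_that("generation is byte-identical given config and seed", {
  cfg <- simulation_config(n_subjects = 60, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- simulation_config(n_subjects = 60, seed = 100)
  expect_false(identical(generate_cohort(cfg)$cohort,
                         generate_cohort(cfg2)$cohort))
})

test_that("degenerate hazards produce all-censored or all-first-interval cohorts", {
  sc_len <- simulation_config(n_subjects = 5)$scheme$n_intervals
  none <- simulation_config(n_subjects = 40, seed = 3,
                            baseline_logit = rep(-Inf, sc_len))
  g <- generate_cohort(none)
  expect_true(all(sapply(g$cohort, `[[`, "event") == 0))

  first <- simulation_config(n_subjects = 40, seed = 3,
                             baseline_logit = c(Inf, rep(-Inf, sc_len - 1)),
                             censor_min = 39, censor_max = 40)
  g2 <- generate_cohort(first)
  expect_true(all(sapply(g2$cohort, `[[`, "event") == 1))
  expect_true(all(sapply(g2$cohort, `[[`, "outcome_age") < 6))
})

test_that("binary marginals calibrate to configured prevalences at large n", {
  g <- generate_cohort(simulation_config(n_subjects = 10000, seed = 2024))
  male <- mean(sapply(g$cohort, `[[`, "sex_male"))
  expect_lt(abs(male - 0.414), 3 * sqrt(0.414 * 0.586 / 10000))
  lith <- mean(sapply(g$cohort, `[[`, "parental_lithium_response"))
  expect_lt(abs(lith - 0.442), 3 * sqrt(0.442 * 0.558 / 10000))
  abuse <- sapply(g$cohort, `[[`, "abuse")
  expect_lt(abs(mean(abuse == "yes") - 0.103), 3 * sqrt(0.103 * 0.897 / 10000))
  expect_lt(abs(mean(abuse == "missing") - 0.380), 3 * sqrt(0.38 * 0.62 / 10000))
})

test_that("interval event fractions converge to the configured hazard without covariates", {
  sc_len <- simulation_config(n_subjects = 5)$scheme$n_intervals
  cfg <- simulation_config(n_subjects = 6000, seed = 31,
                           coefficients = stats::setNames(numeric(0), character(0)),
                           baseline_logit = rep(qlogis(0.1), sc_len),
                           censor_min = 39.5, censor_max = 40)
  g <- generate_cohort(cfg)
  pp <- expand_person_periods(g$cohort, cfg$scheme)
  for (k in c(1, 3, 6)) {
    rows <- pp[pp$interval_index == k, ]
    se <- sqrt(0.1 * 0.9 / nrow(rows))
    expect_lt(abs(mean(rows$event_in_interval) - 0.1), 3.5 * se)
  }
})

test_that("expanding a generated cohort reproduces the recorded truth hazards", {
  cfg <- simulation_config(n_subjects = 150, seed = 8)
  g <- generate_cohort(cfg)
  pp <- expand_person_periods(g$cohort, cfg$scheme)
  truth <- g$truth
  key_pp <- paste(pp$subject_id, pp$interval_index)
  key_tr <- paste(truth$subject_id, truth$interval_index)
  m <- match(key_pp, key_tr)
  expect_false(anyNA(m))
  # recompute hazards from the truth coefficients on the expanded rows
  lp <- cfg$baseline_logit[pp$interval_index]
  for (nm in names(cfg$coefficients))
    lp <- lp + cfg$coefficients[nm] * pp[[nm]]
  expect_equal(unname(plogis(lp)), truth$hazard[m], tolerance = 1e-12)
  # truth survival is the product-limit of truth hazards
  for (id in unique(truth$subject_id)[1:20]) {
    tr <- truth[truth$subject_id == id, ]
    expect_equal(tr$survival, survival_from_hazards(tr$hazard))
  }
})

test_that("true_survival is the closed-form logistic product-limit oracle", {
  sc_len <- simulation_config(n_subjects = 5)$scheme$n_intervals
  cfg <- simulation_config(n_subjects = 5,
                           coefficients = stats::setNames(numeric(0), character(0)),
                           baseline_logit = rep(qlogis(0.1), sc_len))
  path <- as.data.frame(matrix(0, 3, length(pp_covariate_names()),
                               dimnames = list(NULL, pp_covariate_names())))
  expect_equal(true_survival(cfg, path), c(0.9, 0.81, 0.729))
  expect_equal(true_survival(cfg, path[0, ]), numeric(0))
  # a log(2) coefficient exactly doubles the hazard odds
  cfg2 <- simulation_config(n_subjects = 5, coefficients = c(anxiety = log(2)),
                            baseline_logit = rep(qlogis(0.1), sc_len))
  p0 <- path[1, ]
  p1 <- transform(p0, anxiety = 1)
  h0 <- 1 - true_survival(cfg2, p0)
  h1 <- 1 - true_survival(cfg2, p1)
  expect_equal((h1 / (1 - h1)) / (h0 / (1 - h0)), 2, tolerance = 1e-12)
  expect_error(true_survival(cfg2, p0[, setdiff(names(p0), "anxiety")]),
               "anxiety")
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(simulation_config(n_subjects = 0), "n_subjects")
  expect_error(simulation_config(prevalences = c(sex_male = 1.4,
                                                 parental_lithium_response = 0.4,
                                                 abuse_yes = 0.1,
                                                 abuse_missing = 0.3)),
               "\\[0, 1\\]")
  expect_error(simulation_config(coefficients = c(bogus = 1)), "unknown")
  expect_error(simulation_config(interactions = list(list(x1 = "sex_male"))),
               "interaction")
})

test_that("generated antecedents precede the outcome and censoring bounds hold", {
  g <- generate_cohort(simulation_config(n_subjects = 400, seed = 55))
  for (s in g$cohort) {
    if (length(s$onset_ages)) expect_true(all(s$onset_ages < s$outcome_age))
    if (length(s$major_episode_ages))
      expect_true(all(s$major_episode_ages < s$outcome_age))
    expect_gte(s$outcome_age, 5)
    expect_lte(s$outcome_age, 40)
  }
})
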