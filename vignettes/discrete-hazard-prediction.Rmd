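---
title: "Discrete-time hazard prediction for high-risk offspring cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time hazard prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plannsurv)
```

## The prediction problem

Children of a parent with confirmed bipolar disorder are an identifiable
high-risk group, but most of them never develop a bipolar-related major mood
disorder, and onset ages spread across two decades. The clinically useful
question is therefore not *whether* but *when*: given what a clinician knows
about an offspring at a given age — sex, the parent's illness history, and the
antecedent symptoms and diagnoses accumulated so far — what is the probability
of a first major mood disorder diagnosis within the next 1, 3 or 5 years?

plannsurv frames this as discrete-time survival analysis on an **age** time
scale. Follow-up is partitioned into contiguous half-open intervals
$[b_{k-1}, b_k)$ of width 1, 3 or 5 years, and the estimand is the discrete
hazard

$$h_k(x) = \Pr(T \in [b_{k-1}, b_k) \mid T \ge b_{k-1},\; x_k),$$

the conditional probability of diagnosis in interval $k$ for a subject still
undiagnosed and under observation at its start. Event-free probabilities
follow by the product-limit identity $S(k) = \prod_{j \le k} (1 - h_j)$.
Subjects without a diagnosis at their last follow-up visit are censored
there; censoring is handled by the survival formulation itself (at-risk rows
simply stop) and, on the evaluation side, by inverse-probability-of-censoring
weights.

## Person-period expansion and the lag convention

`expand_person_periods()` turns each subject into one row per at-risk
interval with the binary response `event_in_interval`, reducing hazard
estimation to a binary-regression problem that both models share. Two
conventions matter:

* **Censoring within an interval.** A diagnosed subject contributes rows up
  to and including the interval containing the diagnosis; a censored subject
  contributes only intervals fully survived (`interval_end <=` censoring
  age). The partially observed final interval of a censored subject is
  dropped rather than treated as event-free, because "survived the interval"
  is not actually observed there. This is the classical conservative
  treatment; the alternative (keeping the partial interval as a non-event)
  would bias hazards downward at wide interval widths.
* **One-interval lag.** Every time-varying covariate carried by interval
  $k$ — the nine antecedent indicator statuses and the two cumulative mood
  episode counts — is a function of information *strictly before*
  $b_{k-1}$, i.e. status as of the end of interval $k-1$. This guards
  against reverse causality (symptoms recorded in the same interval as the
  diagnosis may be its prodrome rather than its predictor) and means a
  fitted model genuinely predicts the *next* interval from the past.
  Onsets and episodes at or after the outcome age never contribute
  anywhere.

Interval schemes are anchored at age 5 (the minimum enrolment age of the
cohort design this package targets) for every subject, since the time scale
is age rather than time-on-study. Ages are kept as exact decimals. An event
falling exactly on a boundary belongs to the interval starting there.
Childhood abuse enters as two dummies (`abuse_yes`, `abuse_missing`) against
a "no" reference, because the measure is only administered from age 13 and
missingness is an informative, explicitly tabulated category rather than
grounds for exclusion. The interval midpoint age is carried as a
`time_input` column so models can condition on time directly.

## The two hazard models

**Discrete-time logistic survival model** (`fit_hazard_glm()`). The
classical baseline:
$\operatorname{logit} h_k(x) = \alpha_k + \beta^\top x$, with one free
intercept per interval (an unrestricted baseline hazard — no smoothing) and
a single coefficient vector shared across intervals. The shared $\beta$ is
the proportional-odds assumption: a covariate shifts the hazard's log-odds
equally at every age. Fitting is Newton–Raphson with step-halving on the
Bernoulli likelihood, with an optional ridge `ridge/2 * ||theta||^2`
(default `1e-6`) that exists purely for numerical stability under
separation; with `ridge = 0` a degenerate likelihood is reported as an
error rather than silently returning divergent estimates. Continuous
covariates are standardized internally on training statistics and
coefficients are mapped back to the original scale. `time_input` is
excluded from this model's default covariates: the interval midpoint is an
exact linear function of the interval index and is therefore perfectly
collinear with the interval dummies.

**PLANN** (`fit_plann()`). The partial logistic artificial neural network:
a feed-forward network with one hidden layer, sigmoid activations
throughout, fitted to the *same* person-period rows by the *same*
cross-entropy likelihood, plus weight decay. The sigmoid output **is** the
discrete hazard, and time enters as an ordinary input (`time_input`), so
the network can represent both non-linear covariate effects and
non-proportional (age-varying) effects — exactly the two assumptions the
logistic baseline imposes. Differences in predictive performance between
the two models therefore isolate the value of relaxing those assumptions,
everything else (data setup, likelihood, evaluation) being shared.

Training details (all declared package choices; none are prescribed by the
underlying method): full-batch gradient descent with a scale-free adaptive
step (a step that fails to decrease the training objective is halved and
retried, so accepted-epoch training loss is non-increasing), early stopping
on a seeded 10% held-out shuffle split with patience 100, and reversion to
the best held-out epoch. Defaults: 8 hidden units, weight decay 0.01 on the
summed-cross-entropy scale, at most 2000 accepted epochs. Biases are not
decayed, so under extreme regularization predictions collapse to the
marginal event rate (the sensible degenerate limit) rather than to 1/2.
Weight initialization is uniform scaled by fan-in and controlled by the
seed; two fits with identical data and hyperparameters are bit-identical.
Eight hidden units is deliberately modest: with a few hundred events there
is no support for more capacity, and the weight decay plus early stopping
carry the regularization burden.

## Censoring-aware evaluation

All metrics operate on a `prediction_set`: per test subject, the predicted
hazard for every interval of the scheme and the implied step survival
curve, alongside the observed outcome.

* **Time-dependent c-index** (`td_c_index()`): over comparable pairs (an
  event at $t_i$ versus anyone observed beyond $t_i$), the fraction where
  the subject who failed had the lower predicted survival at $t_i$, ties at
  half credit. Predicted survival at an event time is evaluated *through
  the interval containing* $t_i$: within-interval ordering is not
  resolvable in discrete time, and evaluating only completed intervals
  would make all curves identical for events inside the first interval.
* **Brier score** (`brier_score()`): squared distance between predicted
  event-free probability at a fixed age and observed event-free status,
  with IPCW weights from the Kaplan–Meier estimate of the censoring
  distribution (events before the age weighted by $1/G(t_i^-)$, survivors
  by $1/G(t)$, subjects censored earlier contributing zero weight). For
  fixed-age quantities the step curve is evaluated over completed intervals,
  so $S(t)$ estimates $\Pr(T > t)$. The headline figure averages ages 15,
  20 and 25. The unweighted variant is also reported; with no censoring the
  two agree exactly. 0.25 is the chance level.
* **Per-interval AUC** (`interval_auc()`): the incident/dynamic variant —
  among subjects at risk at the interval start (excluding those censored
  within it), rank-sum AUC of the predicted hazard for event-in-interval
  versus survived-interval.
* **Confusion metrics** (`confusion_at_threshold()`): the same risk set
  classified at hazard $\ge$ threshold over the grid
  {0.05, 0.10, 0.15, 0.20} plus a per-interval optimal threshold. "Optimal"
  is Youden's $J = \text{sens} + \text{spec} - 1$, scanned over observed
  hazards with ties broken toward the smaller cut and the returned
  threshold placed midway between the chosen cut and its lower neighbour.
  The optimal threshold is computed on test-fold predictions (mirroring the
  per-interval presentation this package's reports are shaped after), which
  carries a known optimistic bias; treat optimal-threshold rows as
  descriptive, not as honest operating points. PPV is reported as missing —
  never as zero — when no subject crosses the threshold, and degenerate
  risk sets (no events, or no survivors) raise a typed condition that the
  aggregation layer records and excludes from means.

`run_experiment()` orchestrates tenfold stratified cross-validation
(stratified on the event indicator, the standard choice when nothing else
is specified), fitting both models per fold on training rows only.
Standardization constants, model weights and the censoring-distribution
estimate for IPCW are all computed on training folds and applied to test
folds, so no test information leaks into any fitted quantity. Metrics are
averaged across intervals within a fold (where defined), then across folds;
undefined cells are counted and excluded, never imputed. The Wald interval
helpers (`ci_proportion()`, `ci_mean()`) implement the textbook
large-sample formulas exactly as stated, unclipped by default, for the
descriptive cohort table.

## The synthetic cohort generator

The motivating clinical cohort is not publicly deposited, so
`generate_cohort()` provides a synthetic stand-in with the same
*statistical shape*, plus closed-form truth for testing. It emulates:

* time-fixed covariate marginals (41.4% male, 44.2% lithium-responsive
  parent, abuse yes/missing/no at 10.3/38.0/51.7%, parental onset age
  $\mathcal N(25.4, 9.2^2)$ truncated at 10);
* antecedent indicator onsets as per-interval Bernoulli processes whose
  constant yearly hazards $1-(1-p)^{1/16}$ reproduce target lifetime
  prevalences $p$ over a ~16-year observation span, and mood episodes as
  low-rate Poisson counts (cumulative counts averaging ~0.2 by outcome);
* a logistic discrete hazard over yearly intervals with baseline
  $\operatorname{logit} h = -3.28 + 0.095\,(t - 20)$ — onset risk rising
  through adolescence — calibrated analytically (against the censoring
  distribution below) so that roughly 38% of subjects are diagnosed before
  their last visit with median onset near age 20, matching the reference
  cohort's headline fractions. These are cosmetic targets of the default
  configuration, not tested assertions;
* administrative censoring at a last-visit age drawn uniformly on [5, 40].

The generator applies the *same* one-interval lag convention as the
expansion code — each interval's hazard is computed from status strictly
before the interval start, and new onsets are drawn only after the
interval's outcome draw — so expanding a generated cohort and recomputing
hazards from the true coefficients reproduces the recorded truth exactly
(a round-trip the tests assert). Onsets and episodes after the outcome are
discarded, so antecedents are antecedent by construction.

What it deliberately does **not** emulate: covariate dependence (Table-style
marginals are all that is known; all joint structure would be invention),
visit irregularity, diagnostic misclassification, family clustering, and
enrolment-age heterogeneity (every synthetic subject is observed from age
5). Passing recovery and calibration tests on this generator therefore
demonstrates correctness of the machinery, not transportability of any
fitted model to real cohorts. An `interactions` hook injects product terms
into the true hazard for experiments where the truth is deliberately
outside the logistic model's class.

## Numerical choices and degenerate inputs

* Interval membership uses half-open intervals with a `1e-9` age tolerance
  at boundaries; an event exactly on a boundary belongs to the interval
  starting there.
* The GLM refuses to extrapolate intercepts for intervals that had no
  at-risk training rows; `predict(..., fill = "carry")` substitutes the
  nearest estimated intercept, used when composing whole-horizon survival
  curves in cross-validation (a test fold can contain the oldest subject).
* Youden-threshold ties break toward the smaller cut; all-tied hazards
  return the smallest candidate flagged `degenerate`.
* IPCW weights refuse to divide by a zero censoring-survivor estimate and
  name the offending age.
* `stratified_folds()` deals shuffled events and non-events round-robin, so
  fold event counts differ by at most one; all randomness (folds, network
  initialization, generator) is seed-derived and restores the caller's RNG
  state.

## Problem sizes used in the test suite

The simulation-based checks run at sizes chosen to make their Monte-Carlo
error small relative to the assertion: coefficient recovery at n = 5000
(tolerance ±0.1), model-comparison checks at n = 3000, null-calibration at
n = 600 across five seeds, and oracle-equivalence sweeps at n ≤ 20 against
exhaustive enumeration. Null calibration is asserted with a one-sample
t-test against 0.5 across seeds — the direct reading of "within Monte-Carlo
error" — rather than a fixed band, because the per-seed dispersion of a
c-index on a few hundred test subjects is itself ~0.1.

## Known limitations

* The discrete c-index convention (interval-level survival comparison) can
  differ slightly from continuous-time implementations at tied or
  within-interval event times.
* Optimal-threshold rows are test-fold-optimized and optimistically biased
  by construction.
* The generator's covariate independence means interaction- or
  correlation-driven phenomena in real cohorts are out of its reach unless
  injected explicitly.
* Brier ages outside a narrow scheme (e.g. age 25 under a scheme ending at
  24) are silently dropped from the mean; the per-fold breakdown records
  which ages entered.
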