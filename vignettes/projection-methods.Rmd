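---
title: "Projecting risk-factor prevalence by multiple imputation of future survey waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting risk-factor prevalence by multiple imputation of future survey waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevproj)
```

## The model

`prevproj` projects the prevalence of six risk factors — current smoking,
leisure time sedentary lifestyle, hypertension, elevated total cholesterol,
the three BMI categories, and diabetes — from a series of cross-sectional
health examination surveys, by treating everything unobserved as missing
data in one person-level frame and filling it with chained-equations
multiple imputation:

1. **The frame.** One row per invited individual in every observed wave
   (demographics from the sampling frame are always present; survey-derived
   columns are missing for unit non-respondents and item-wise for
   participants), plus pseudo-sample rows for each projection year whose sex
   and age follow a population projection and whose every other column is
   missing.
2. **Conditional models.** Each incomplete variable gets a conditional
   model given the others: logistic regression for binary targets,
   polytomous (multinomial) logistic regression for the BMI category and
   education. Survey year enters as a continuous covariate, so a model
   fitted on the observed waves extrapolates to the projection years.
3. **The chain.** Per stream, missing cells are initialised by resampling
   observed values of the same variable (within the same sex stratum), and
   the targets are then revisited for a fixed number of sweeps: refit on
   originally observed rows, draw parameters to propagate estimation
   uncertainty, redraw the missing cells. Observed cells are never touched.
4. **Pooling.** Prevalence per indicator, sex and year is the mean over the
   `m` completed datasets of the within-imputation proportion. Wilson score
   intervals serve as prediction intervals; the between-imputation variance
   of the proportion is reported alongside, not silently merged into the
   interval.

The method's central assumption is missingness at random given the modelled
covariates — for future rows this amounts to assuming the fitted secular
trends and covariate dependencies continue to hold. A projection is an
extrapolation of the observed history, not a forecast of policy effects.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `m` (`mice_config`) | 100 | datasets | matches common practice for stable pooled proportions; tests use 10–20 to keep runtimes in seconds–minutes |
| `iterations` | 10 | sweeps | chain means stabilise well before 10 in all scenarios we test (see the stabilisation test) |
| `parameter_draw` | posterior (logistic), bootstrap (polytomous) | — | posterior-normal draws are cheap and accurate for the well-conditioned logistic fits; the bootstrap avoids relying on the multinomial Hessian, and both modes are selectable |
| `n_per_year` (`future_sample_spec`) | 10,000 | persons/year | large enough that pseudo-sample binomial noise is small against parameter uncertainty |
| projection years | 2020–2040 annual | — | a 5-year grid is available and is what the tests use |
| Wilson `level` | 0.95 | — | conventional |
| knots (`default_year_knots`) | 10th/50th/90th percentiles of observed years | calendar years | with five equally sized waves these are the first, middle and last wave; 3 knots is the smallest restricted-cubic-spline basis |
| thresholds (`indicator_thresholds`) | 140/90 mmHg, 5 mmol/l, 48 mmol/mol, BMI 25/30 | clinical units | the standard clinical cut-offs; intervals half-open with the lower bound included |
| smoking recency window | last smoked within 30 days | — | the questionnaire wording does not pin the cut; 30 days is the standard survey convention and the window is configurable |

## What the synthetic generator emulates — and what it does not

`scenario_config()` defaults encode the study conditions of the Finnish
1997–2017 series: five waves every five years; invited samples of
5000/4999/4000/4000/1635 men and 5000/5000/4000/4000/1542 women; published
questionnaire response rates (e.g. 67.9% for men in 1997) and examination
participation rates, with examination participants nested within
questionnaire respondents; ages 25–64 uniform over five areas; logit-linear
secular trends per indicator with additive sex and age effects; obesity
raising the diabetes and hypertension log-odds (defaults 1.0 and 0.8); 2%
item non-response per column (the study's per-item rates are not published,
so this is a configurable placeholder); and a diabetes indicator forced
missing in 1997 and 2007, where no HbA1c assay existed, so non-medicated
participants are undecidable.

The generator works at the indicator level (binary indicators and the
3-category BMI), which is also what the engine imputes; raw measurements
(blood pressures, cholesterol, anthropometry, HbA1c) appear only in the
`derive_*` functions that map real raw tables to indicators. It does not
attempt Finnish geography, true variable codings, laboratory error, or
measurement averaging across repeated readings (a pre-averaged value is
accepted). Consequently, passing tests demonstrate that the pipeline
recovers the truth of a logit-linear world with MAR missingness; they
cannot certify behaviour under model misspecification or informative
non-response in real data.

Item non-response is MCAR by default with an optional MAR-on-age/sex
mechanism (`item_mar`), since MAR is what the imputation assumes and both
regimes are needed for testing. Ages are drawn as integers (completed
years) but treated as continuous downstream. One master seed drives
deterministic per-wave and per-mechanism substreams, so adding a wave never
perturbs earlier waves, and per-imputation substreams make results
invariant to execution order.

## Numerical choices

* **Logistic fitter.** In-package IRLS with the observed-information
  covariance (it matches `stats::glm` to 1e-6 in tests). Separation or rank
  deficiency triggers an escalating ridge penalty starting at `1e-4 * n`
  (intercept unpenalised), flagged on the fit rather than aborting — sparse
  cells are expected once future pseudo-samples enter.
* **Polytomous fitter.** `nnet::multinom` behind the module surface, with
  the first level as reference (its log-odds identically zero); prediction
  is a plain softmax of the coefficient matrix. Bootstrap redraws resample
  until every category is present (25 attempts, then error).
* **Posterior draws.** Cholesky of the covariance; a non-positive-definite
  covariance is repaired by eigenvalue clipping at 1e-10. An all-zero
  covariance returns the MLE exactly.
* **Spline trend.** Natural cubic spline basis via `splines::ns` with the
  outer knots as boundary knots: `k` knots give `k − 1` columns including
  the linear span, and the basis is linear beyond the boundary knots, so
  extrapolated trends cannot develop cubic tails.
* **Model selection.** Exhaustive search over the optional-predictor
  subsets (at most a few hundred candidates at this scale; removes path
  dependence), linear year form first, then linear-vs-spline within the
  winning subset. BIC ties within 1e-9 go to the smaller model, then to the
  lexicographically first predictor set; the spline must strictly win. The
  non-linearity decision is made by BIC comparison (not a likelihood-ratio
  test) for internal consistency with the subset search. Selection uses
  complete cases of the observed waves only — future rows carry no outcome
  information — which is an acknowledged approximation since selection
  precedes imputation.
* **Visit order.** Ascending fraction of missingness (stabilises early
  sweeps); configurable.
* **Future demographics.** Deterministic largest-remainder allocation of
  each year's `n_per_year` rows to the (sex, age) cells by default — one
  fewer Monte-Carlo layer; multinomial sampling mode retained for variance
  studies.
* **Wilson `n`.** The stratum row count (per sex: half of the pseudo-sample
  per year). What `n` should enter a prediction interval for a pooled
  proportion is genuinely open; we keep the interval a pure Wilson interval
  and emit the between-imputation variance separately.
* **Degenerate inputs.** Empty strata are dropped with a warning in
  pooling; a target with no observed values cannot be initialised and
  errors; a single observed class in a logistic target errors with the
  class named; empty categories in a polytomous target error with the
  category named.

## Design choices where the design was open

* **Indicators, not raw measurements, are imputed.** The samplers are
  binary/categorical, matching the logreg/polyreg model families; imputing
  derived indicators keeps the chain in that family.
* **Structural HbA1c unavailability** is represented at the indicator
  level: the diabetes indicator is forced missing for the affected waves in
  the generator, and `derive_diabetes()` returns missing for non-medicated
  participants of those waves (coding them 0 would bias the trend).
* **Future covariates** (area, marital status, education) are treated as
  imputable targets with demographic-only models; a fixed-marginal
  alternative can be expressed by supplying the values directly in the
  future frame.
* **Unit non-respondents' indicators** are missing (three-valued OR
  derivation), so observed-year prevalences computed on the imputed full
  invited sample are non-response corrected.

## Problem sizes in the shipped tests

The validation suite uses scaled-down study conditions chosen once as
realistic for their purpose: MCAR-neutrality with five waves of 2,000
invited (30% deletion, m = 20, 10 iterations); trend recovery with five
waves of 3,000 and future pseudo-samples of 2,000/year on a 5-year grid
(m = 20); selection consistency at n = 5,000 with 100 replicates; the
polarisation scenario with five waves of 4,000 and a ±0.012/yr
overweight/obese logit drift around a 45% normal-weight share, whose
analytic normal-share wobble is under one percentage point across
1997–2040. `scripts/acceptance.R` re-runs the same computations from
scratch under a caller-supplied seed.

## Known limitations

* Uncertainty in the population projection itself is not propagated.
* The Wilson band on a pooled proportion understates total uncertainty when
  between-imputation variance is large (notably diabetes-like low-prevalence
  indicators); both quantities are reported so users can combine them
  explicitly.
* Projections inherit the fitted trend family: a logit-linear (or
  restricted-cubic-spline) trend fitted on five waves can misrepresent
  saturating or reversing real-world trends.
* No predictive-mean matching, continuous-variable samplers, multilevel
  imputation, interaction-term search, or translation of risk-factor
  prevalence into disease incidence.
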