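---
title: "Modelling the natural history of fatty liver by microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the natural history of fatty liver by microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcourse)
```

## The model

`flcourse` implements an individual-level, discrete-time state-transition
model of fatty liver (hepatic steatosis diagnosed by ultrasonography) in
adult men.  Each member of a cohort carries a binary disease state and a
set of continuous risk factors.  Once a year, in this order:

1. the member's risk factors are dichotomized at clinical cut-points
   (BMI ≥ 25 kg/m², LDL-C/HDL-C ratio ≥ 2);
2. next year's fatty-liver state is drawn Bernoulli at the transition
   probability given the *current* state and flags — the predictors
   before transition;
3. the modelled continuous risk factors are advanced by their stochastic
   annual update rules;
4. age increases by one.

The transition probability is a main-effects logistic surface,

$$\operatorname{logit} P(FL_{t+1} = 1) \;=\; \beta_0 + \beta_{FL}\,FL_t +
  \beta_{BMI}\,[BMI_t \ge 25] + \beta_{ratio}\,[LDL/HDL_t \ge 2],$$

with no interactions.  The published 8-cell transition table this package
ships as `reference_transition_table()` is additive on the log-odds scale
to within printing precision: fitting the four coefficients to all eight
cells by unweighted least squares on the logit scale
(`fit_table_main_effects()`) reproduces every cell to better than ±0.005,
and any one of the three no-prior-disease risk cells can be predicted
from the other seven to the same accuracy.  The least-squares fit is
unweighted because per-cell sample sizes are not published; with an
(almost) exactly additive table, weighting would not change the result
appreciably.

Prevalence projections are Monte Carlo: the default protocol is 10
replicate runs of the whole cohort at one-year intervals, reporting the
across-run mean prevalence and a ±2 SD band as the model's uncertainty.
The projected population is closed — no entry, exit or death — so
prevalences at old ages are, if anything, slightly overestimated.

For fixed flags the disease state is a two-state Markov chain with
incidence `p01` and persistence `p11`; its stationary prevalence
`p01 / (p01 + 1 − p11)` (`stationary_prevalence()`) is the closed-form
oracle against which the simulator's long-run behaviour is tested.

## Annual update rules

The exact update algorithms behind the source study are unpublished, so
the package adopts the simplest form consistent with their description —
a stochastic first-order autoregression with an age profile, fitted from
panel data by ordinary least squares:

$$V_{t+1} = a + b\,V_t + c\,\mathrm{age} + d\,(\mathrm{age}-k)_+ +
  \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2).$$

The hinge at age `k` (default 50–55) lets the expected life-course rise
to middle age and decline afterwards, the shape BMI follows in national
survey data.  Two design points deserve comment:

* **The ratio is updated as one variable.**  The LDL-C/HDL-C ratio, not
  its components, predicts the disease state, so the simulator carries a
  single `ratio` series fitted and evolved directly.
* **Skewed variables are updated on the log scale.**  BMI and the
  cholesterol ratio are strictly positive and right-skewed.  A Gaussian
  natural-scale autoregression drives the marginal towards symmetry,
  which biases the fraction beyond an above-mean cut-point upward by
  several percentage points over a 40-year horizon.  Fitting the
  autoregression to `log V`
  (`fit_covariate_update(..., log = TRUE)`, the pipeline default for BMI
  and the ratio) keeps the long-run marginal right-skewed and removes
  the bias; residuals remain Gaussian, on the log scale.

Residual draws are truncated to physiologic ranges (BMI 12–60 kg/m²,
ratio 0.05–10) by inverse-CDF sampling.  The inverse-CDF form matters:
it consumes exactly one uniform per draw, so two simulation arms run
with the same seed stay in random-number lockstep even when truncation
triggers, which is what makes paired sensitivity contrasts exact at zero
perturbation.

Perturbation semantics: a sensitivity multiplier `1 + δ` scales each
year's *predicted* (pre-residual) update, compounding over the horizon.
A ±1% annual BMI perturbation therefore accumulates to a large long-run
shift (≈ ±20% of the level at persistence 0.95), which is why annual
update perturbations dominate initial-composition changes late in the
projection.  Perturbing the realized value (residual included) or the
coefficients themselves would be alternative readings; the predicted
value is the implemented one.

## The synthetic cohort generator

No public accession of the motivating data set exists, so every
downstream stage is exercised against synthetic panels whose statistical
structure matches what the analysis assumes.  The generator
(`generate_population()`) emulates an occupational health-examination
population of Japanese men aged 20–69:

* **Marginals.**  Continuous risk factors are drawn around piecewise-
  linear age profiles.  BMI, TG and HbA1c use a shifted log-normal
  family; the rest are symmetric.  The skew is load-bearing: a BMI
  marginal with mean 23.3 and SD 3.6 kg/m² must coexist with ~27% of the
  cohort at ≥ 25 kg/m² — a symmetric normal puts ~32% there.
  `calibrate_skew_shift()` solves for the log-normal shift hitting a
  target category fraction (for HbA1c, the target is a realistic
  diabetic tail of 1–2% at ≥ 6.5%, which a symmetric normal at mean
  5.2–5.4 essentially cannot produce).
* **Dynamics.**  Covariates evolve by the mean-reverting autoregression
  above with residual SD `sd·√(1−ρ²)`, which preserves the marginal
  moments along the age profile.  LDL-C and HDL-C share correlated draws
  (default correlation −0.2, a stand-in: the source population's
  covariate correlations are unpublished); the ratio is always computed,
  never generated.
* **Disease state.**  Baseline status is one Bernoulli draw from a
  logistic in the dichotomized covariates whose slopes are the
  main-effects fit to the per-cell *stationary* log-odds of the true
  transition model, with the intercept calibrated to the target baseline
  prevalence; thereafter the state evolves by the transition model.
  This makes baseline prevalence, flag–state correlation and transition
  dynamics mutually consistent, so projections from cohorts of different
  baseline ages land on the same age-specific equilibrium (the
  time-shift consistency the validation module checks).
* **Open population.**  9% of members enter and 6% leave per year;
  members leave the programme after age 69 (retirement).  Fatty-liver
  availability is age-banded (`apply_missingness()`: 0% at 20–29, 9.1%
  at 30–39, 95.5% at 40–69), and the missing statuses are imputed by a
  same-year logistic regression fitted to observed-status records aged
  30–69 (`fit_fl_imputation()` / `impute_missing_fl()`).
* **Lifestyle booleans** (smoking, drinking, exercise, shift work) are
  drawn once per person and held fixed — no transition rules for them
  are available — and they carry no effect on the disease state in the
  generator, matching their exclusion from the final transition model.

Two presets encode the study conditions: `study_population_config()`
(~2000 men 20–69 per wave, five waves, the published clinical summary
statistics, baseline prevalence 28%) and `cohort2_config()` (2162 men
aged 30–39, the younger marginals, baseline prevalence 19.8%, BMI flag
calibrated to 27.0%).

What passing tests on these panels do **not** show: fidelity of the
generator beyond first/second moments and category fractions (the true
joint distribution, measurement error, within-person missingness
patterns and secular trends are not emulated), nor recovery of the
source study's actual fitted coefficients, which were never published.

## Validation and sensitivity protocols

* **V-1 calibration**: a complete-case cohort (members present in every
  wave with no missing field) is projected from its first wave; each
  observed yearly prevalence of fatty liver and of the two flags should
  fall within ±2 SD of the simulated mean.  The acceptance rule is ≥ 80%
  of year–quantity cells covered — the source's criterion ("almost
  within" the band) is visual and unquantified, so the 80% rule is this
  package's formalization; note a 2 SD band over 10 runs is itself a
  noisy estimate.
* **V-2 time shift**: cohorts with baseline ages 30–39, 40–49 and 50–59
  are projected to ages 70–79 and aligned on cohort mean age; within
  each shared decade band the band means of two cohorts must differ by
  at most `2(SD_A + SD_B)` — a conservative, assertable version of
  "the trajectories almost overlapped".
* **V-3 external comparison**: simulated band prevalences are compared
  against user-supplied external survey values (per-band difference and
  inside/outside the observed min–max range).  External values are
  config inputs, not bundled data.
* **S-1 initial composition**: stratified resampling with replacement
  sets a category's baseline prevalence to (1 ± 20/40%) of its original
  value at unchanged cohort size.  Changes are reported in percentage
  points of fatty-liver prevalence: the mean change while the cohort
  mean age is 50–59 (the headline band), the largest single-year
  absolute change, and a decade-band-smoothed maximum (`max_abs_band`)
  that suppresses the single-year Monte Carlo noise a 10-run protocol
  leaves behind.  The signed changes over the first and last five
  projection years (`change_start`, `change_final`) quantify how
  initial-composition effects decay while update-perturbation effects
  grow.
* **S-2 update perturbation**: each variable's annual updates are scaled
  by 1 ± 0.5/1%, with common random numbers against the unperturbed
  run.  The "maximum amount of change" is reported as an absolute value
  (whether the source intended signed maxima is ambiguous; absolute is
  implemented).

## Numerical choices and degenerate inputs

* Backward elimination drops the single largest-p term per step (ties by
  term order) until all p < α = 0.05.  P-values are likelihood-ratio
  (`drop1`, χ²) rather than Wald, so that near-separated data do not
  produce meaningless large p-values for strong predictors; genuinely
  separated data (a fitted log-odds coefficient beyond 15) are rejected
  with a diagnostic, as are panels with fewer than 50 transitions.
* Transition-model risk coefficients are constrained non-negative; a
  zero coefficient represents a term eliminated during selection.
* `stationary_prevalence()` rejects the absorbing-degenerate chain
  (`p01 = 0`, `p11 = 1`), which has no unique fixed point.
* Boundary handling of the cut-points is inclusive-≥ for BMI, LDL-C,
  ratio, TG, SBP and HbA1c and strict-< for HDL-C, exactly as the
  clinical definitions state them.
* An all-zero-noise generator configuration (persistence 1, residual SD
  0, closed population) freezes every member's covariates — the
  degenerate case used to test panel plumbing.

## Problem sizes

The test suite and the reproduction script run the generator at 2000
persons per wave for five waves (≈ 9,500 person-years, ≈ 7,000
person-transitions), project cohorts of ≈ 850–2,162 members over ≈ 44
years with 10 Monte Carlo runs, and use 2,000 members × 200 years for
the stationary-distribution checks and ≥ 10,000 person-transitions for
parameter-recovery checks.  These sizes put Monte Carlo standard errors
well inside the tolerances being asserted while keeping a full run in
the low minutes on one CPU.

## Known limitations

* Closed-population projection without mortality overestimates
  prevalence at older ages; the package deliberately stops at the 70–79
  band.
* The scalar autoregressive ratio update is a 1-D compression of 2-D
  lipid dynamics; its one-step conditional variance is larger than the
  truth's even though the marginals match.
* The imputation model assumes the missing-status mechanism is ignorable
  given the flags and age (true by construction in the generator,
  an assumption for real data).
* TG, SBP, HbA1c and the lifestyle factors have no update models — they
  are carried forward unchanged during projection, which is irrelevant
  to the disease state (they are not in the transition model) but means
  their simulated trajectories should not be interpreted.
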