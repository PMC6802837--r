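# flcourse

Individual-level microsimulation of the **natural history of fatty
liver** (hepatic steatosis diagnosed by ultrasonography) in adult
Japanese men, for epidemiologists and health-services modellers who want
to project how the prevalence of the condition evolves as a cohort ages,
and which modifiable risk factors drive that life-course.

## The model

Each cohort member carries a binary disease state and a set of annually
updated risk factors.  The state transition is a main-effects logistic
model on the predictors *before* transition,

```
logit P(FL[t+1] = 1) = β₀ + β_FL·FL[t] + β_BMI·1{BMI[t] ≥ 25} + β_ratio·1{LDL/HDL[t] ≥ 2},
```

which induces an 8-cell transition table over (prior status, BMI ≥ 25
kg/m², LDL-C/HDL-C ≥ 2).  Continuous risk factors advance by stochastic
first-order autoregressive update rules with piecewise-linear age
profiles, fitted from panel data.  Prevalence projections are Monte
Carlo (10 replicate runs, mean ± 2 SD band).  For fixed flags the state
is a two-state Markov chain whose stationary prevalence
`p01/(p01 + 1 − p11)` serves as an analytic oracle for the simulator.

Because no public version of the motivating data set exists, the package
includes a calibrated synthetic-cohort generator (open enrollment,
attrition, retirement at 69, age-banded availability of the
ultrasonography diagnosis, logistic imputation of missing status) so the
whole pipeline — generate → impute → fit → simulate → validate →
sensitivity — is reproducible and testable end to end.

## Worked example

```r
library(flcourse)

# The published 8-cell transition surface is additive on the log-odds
# scale: a main-effects fit reproduces every cell to ±0.005.
model <- fit_table_main_effects(reference_transition_table())
model
#> <fl_transition_model> logit P(FL') = -3.445 + 4.061*FL + 0.893*[BMI>=25] + 0.921*[LDL/HDL>=2]

# Synthetic study population (2000 men aged 20-69 per wave, 5 waves),
# age-banded status availability, imputation, model derivation from the
# observed transitions.
pop      <- generate_population(study_population_config(seed = 1))
observed <- apply_missingness(pop, seed = 2)
panel    <- impute_missing_fl(observed, fit_fl_imputation(observed), seed = 3)
fl_fit   <- fit_fl_transition(observed)
updates  <- list(bmi   = fit_covariate_update(observed, "bmi",   age_knot = 50, log = TRUE),
                 ratio = fit_covariate_update(observed, "ratio", age_knot = 50, log = TRUE))
fl_fit
#> <fl_transition_model> logit P(FL') = -3.382 + 4.003*FL + 1.110*[BMI>=25] + 0.858*[LDL/HDL>=2]
#>   fitted on 4428 person-transitions; eliminated: none

# Project a cohort of 2162 men aged 30-39 until they reach 70-79.
cohort2 <- generate_population(cohort2_config(seed = 4))
traj <- simulate_lifecourse(cohort2, fl_fit, updates,
                            simulation_config(n_runs = 10, seed = 5))
traj
#> <fl_trajectory> 2162 members, 10 runs, 45 projection years; FL 19.1% -> peak 31.0% -> 21.9%

# One-way sensitivity: ±1% annual-update perturbations, paired seeds.
sens <- sweep_updates(cohort2, fl_fit, updates,
                      simulation_config(n_runs = 10, seed = 5),
                      deltas = c(-0.01, 0.01))
as.data.frame(sens)[, c("axis", "factor", "change_50s")]
#>       axis factor change_50s
#> 1 baseline   0.00        0.0
#> 2      bmi  -0.01       -7.5
#> 3      bmi   0.01       11.5
#> 4    ratio  -0.01       -1.6
#> 5    ratio   0.01        1.6
```

Reading the output: the fitted transition model recovers the generating
surface (prior disease adds ≈ 4 log-odds units; each risk flag ≈ 0.9–1.1);
the cohort's prevalence rises from 19.1% to a peak of 31.0% while its
mean age crosses the 40s–50s, then declines to 21.9% by 70–79; and a ±1%
compounding perturbation of the annual BMI updates moves the prevalence
at ages 50–59 by −7.5/+11.5 percentage points — several times the effect
of the same perturbation applied to the cholesterol-ratio updates
(∓1.6) — which is the model's central claim: sustained BMI control
dominates lipid-ratio control for fatty-liver prevention.

`run_study()` (or `Rscript inst/scripts/run_study.R --out dir --seed 1`)
executes the full pipeline and writes models (YAML), the transition
table, trajectories, validation reports and sensitivity grids (CSV),
life-course figures (PNG) and a deterministic manifest.

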