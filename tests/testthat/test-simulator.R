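test_that("an absorbing cell keeps every member in the fatty-liver state", {
  mem <- frozen_members(300, fl = 1, bmi_flag = TRUE, ratio_flag = TRUE)
  absorbing <- fl_transition_model(-5, 30, 0.5, 0.5)  # cell (1,1,1) ~ 1
  withr::with_seed(1, {
    for (t in 1:25) mem <- simulate_year(mem, absorbing, identity_updates())
  })
  expect_true(all(mem$fl == 1L))
  expect_equal(mem$age[1], 65L)
})

test_that("frozen-cell long-run prevalence matches the stationary oracle", {
  truth <- fit_table_main_effects(ref_cells())
  mem <- frozen_members(1000, fl = 0, bmi_flag = FALSE, ratio_flag = FALSE)
  withr::with_seed(77, {
    for (t in 1:150) mem <- simulate_year(mem, truth, identity_updates())
  })
  target <- stationary_prevalence(
    transition_probability(truth, 0, 0, 0),
    transition_probability(truth, 1, 0, 0))
  tol <- 3 * sqrt(target * (1 - target) / 1000)
  expect_lt(abs(mean(mem$fl) - target), tol)
})

test_that("perturbation multiplies the predicted update", {
  # noise-free update predicting 25.0; +1% perturbation gives 25.25
  upd <- list(bmi = covariate_update_model("bmi", c(intercept = 25, slope = 0), 0),
              ratio = covariate_update_model("ratio", c(intercept = 2, slope = 0), 0))
  mem <- data.frame(age = 40L, fl = 0L, bmi = 23, ratio = 1.9)
  out <- withr::with_seed(1, simulate_year(mem, fl_transition_model(-3, 4, 1, 1),
                                           upd, perturbation = c(bmi = 1.01)))
  expect_equal(out$bmi, 25.25)
  expect_equal(out$ratio, 2)
})

test_that("life-course projection is deterministic and closed", {
  cohort <- generate_population(cohort2_config(n_per_year = 300, seed = 2))
  truth <- fit_table_main_effects(ref_cells())
  upd <- list(
    bmi = covariate_update_model("bmi", c(intercept = 1.2, slope = 0.95), 0.8),
    ratio = covariate_update_model("ratio", c(intercept = 0.4, slope = 0.8), 0.3))
  cfg <- simulation_config(n_runs = 4, horizon = 12, seed = 9)
  t1 <- simulate_lifecourse(cohort, truth, upd, cfg)
  t2 <- simulate_lifecourse(cohort, truth, upd, cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$fl_mean >= 0 & t1$fl_mean <= 1))
  expect_true(all(t1$fl_sd >= 0))
  expect_identical(t1$fl_sd[1], 0)   # all runs share the baseline
  # single run: SD identically zero
  t3 <- simulate_lifecourse(cohort, truth, upd,
                            simulation_config(n_runs = 1, horizon = 5, seed = 9))
  expect_true(all(t3$fl_sd == 0))
  # closed population: member count is invariant year over year
  mem <- baseline_state(cohort)[c("age", "fl", "bmi", "ratio")]
  n0 <- nrow(mem)
  withr::with_seed(3, {
    for (t in 1:5) {
      mem <- simulate_year(mem, truth, upd)
      expect_equal(nrow(mem), n0)
    }
  })
  expect_error(simulate_lifecourse(cohort, truth, upd,
                                   simulation_config(horizon = 0)), "horizon")
  expect_error(simulate_year(mem, truth, upd["bmi"]), "ratio")
})

test_that("the 50s-band prevalence responds monotonically to BMI perturbation", {
  cohort <- generate_population(cohort2_config(n_per_year = 700, seed = 5))
  truth <- fit_table_main_effects(ref_cells())
  pop <- generate_population(study_population_config(n_per_year = 1500,
                                                     years = 5, seed = 5))
  upd <- list(bmi = fit_covariate_update(pop, "bmi", age_knot = 50, log = TRUE),
              ratio = fit_covariate_update(pop, "ratio", age_knot = 50,
                                           log = TRUE))
  mults <- c(0.99, 0.995, 1, 1.005, 1.01)
  band_prev <- vapply(mults, function(m) {
    cfg <- simulation_config(n_runs = 5, seed = 21,
                             perturbation = c(bmi = m))
    tr <- simulate_lifecourse(cohort, truth, upd, cfg)
    mean(tr$fl_mean[tr$mean_age >= 50 & tr$mean_age < 60])
  }, numeric(1))
  # paired seeds: response nondecreasing up to a small Monte Carlo slack
  expect_true(all(diff(band_prev) > -0.003))
  expect_gt(band_prev[5], band_prev[1])
})

test_that("band coverage flags years outside +/- 2 SD", {
  cohort <- generate_population(cohort2_config(n_per_year = 250, seed = 3))
  truth <- fit_table_main_effects(ref_cells())
  upd <- list(
    bmi = covariate_update_model("bmi", c(intercept = 1.2, slope = 0.95), 0.8),
    ratio = covariate_update_model("ratio", c(intercept = 0.4, slope = 0.8), 0.3))
  tr <- simulate_lifecourse(cohort, truth, upd,
                            simulation_config(n_runs = 6, horizon = 8, seed = 2))
  obs_eq <- data.frame(step = tr$step, value = tr$fl_mean)
  expect_true(all(band_coverage(tr, obs_eq)))
  k <- 5L
  obs_out <- data.frame(step = tr$step[k],
                        value = tr$fl_mean[k] + 3 * tr$fl_sd[k])
  expect_false(band_coverage(tr, obs_out)[1])
  expect_error(band_coverage(tr, data.frame(step = 99, value = 0.2)),
               "not in trajectory")
})

test_that("the 2 SD band covers self-generated observations most of the time", {
  # observations drawn from the simulator's own model: per-year coverage
  # of the 10-run band is at least 80% over replicates
  cohort <- generate_population(cohort2_config(n_per_year = 200, seed = 14))
  truth <- fit_table_main_effects(ref_cells())
  upd <- list(
    bmi = covariate_update_model("bmi", c(intercept = 1.2, slope = 0.95), 0.8),
    ratio = covariate_update_model("ratio", c(intercept = 0.4, slope = 0.8), 0.3))
  n_rep <- 200
  covered <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    tr <- simulate_lifecourse(cohort, truth, upd,
                              simulation_config(n_runs = 10, horizon = 4,
                                                seed = 3000 + 2 * r))
    obs <- simulate_lifecourse(cohort, truth, upd,
                               simulation_config(n_runs = 1, horizon = 4,
                                                 seed = 3001 + 2 * r))
    cov <- band_coverage(tr, data.frame(step = 1:4, value = obs$fl_mean[2:5]))
    covered[r] <- mean(cov)
  }
  expect_gte(mean(covered), 0.80)
})
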