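test_that("stationary prevalence matches the closed form and a brute-force chain", {
  # fixed point p01 / (p01 + 1 - p11), frozen from the closed form
  expect_equal(stationary_prevalence(0.031, 0.649), 0.031 / 0.382)
  expect_equal(stationary_prevalence(0.164, 0.919), 0.164 / 0.245)
  expect_equal(stationary_prevalence(0.5, 0.5), 0.5)
  # brute-force 1e6-step chain agrees
  sim <- chain_sim_oracle(0.031, 0.649)
  expect_lt(abs(sim - 0.031 / 0.382), 0.002)
  expect_error(stationary_prevalence(0, 1), "degenerate")
  expect_error(stationary_prevalence(-0.1, 0.5), "p01")
})

test_that("transition probabilities reproduce the published surface", {
  m <- fit_table_main_effects(ref_cells())
  expect_lt(abs(transition_probability(m, 0, 0, 0) - 0.031), 0.005)
  expect_lt(abs(transition_probability(m, 1, 1, 1) - 0.919), 0.005)
  z <- fl_transition_model(0, 0, 0, 0)
  expect_equal(unname(transition_probability(z, c(0, 1), c(0, 1), c(1, 0))),
               c(0.5, 0.5))
  expect_error(transition_probability(m, 2, 0, 0), "0 or 1")
})

test_that("build_table is monotone in every index and saturates correctly", {
  m <- fit_table_main_effects(ref_cells())
  tab <- build_table(m)
  # monotone nondecreasing in each of the three indices
  for (idx in c("fl", "bmi", "ratio")) {
    others <- setdiff(c("fl", "bmi", "ratio"), idx)
    for (a in 0:1) for (b in 0:1) {
      sub <- tab[tab[[others[1]]] == a & tab[[others[2]]] == b, ]
      sub <- sub[order(sub[[idx]]), ]
      expect_true(all(diff(sub$prob) >= 0))
    }
  }
  expect_true(all(build_table(fl_transition_model(0, 0, 0, 0))$prob == 0.5))
  sat <- build_table(fl_transition_model(-3.4, 60, 0.9, 0.9))
  expect_true(all(sat$prob[sat$fl == 1] > 0.999))
})

test_that("main-effects fit matches an explicit normal-equations oracle", {
  cells <- ref_cells()
  oracle <- ls_logit_oracle(cells)
  m <- fit_table_main_effects(cells)
  expect_equal(m$beta0, unname(oracle[1]), tolerance = 1e-8)
  expect_equal(m$beta_fl, unname(oracle[2]), tolerance = 1e-8)
  expect_equal(m$beta_bmi, unname(oracle[3]), tolerance = 1e-8)
  expect_equal(m$beta_ratio, unname(oracle[4]), tolerance = 1e-8)

  # a table generated exactly from a main-effects model is recovered exactly
  gen <- fl_transition_model(-2.5, 3, 0.8, 0.6)
  rec <- fit_table_main_effects(build_table(gen))
  expect_equal(rec$beta0, gen$beta0, tolerance = 1e-10)
  expect_equal(rec$beta_fl, gen$beta_fl, tolerance = 1e-10)

  # designs not spanning all indices are rejected
  expect_error(fit_table_main_effects(cells[cells$fl == 0, ]),
               "rank-deficient")
  expect_error(fit_table_main_effects(cells[1:3, ]), "at least 4")
})

test_that("backward elimination keeps real predictors and drops null ones", {
  truth <- fit_table_main_effects(ref_cells())
  # a flag with zero true coefficient is eliminated at alpha = 0.05 in at
  # least 90% of replicates (its p-value is uniform under the null)
  n_rep <- 200
  dropped <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    pan <- transitions_panel(1500, truth, seed = 5000 + r,
                             extra_null_flag = TRUE)
    fit <- suppressWarnings(
      fit_fl_transition(pan, candidate_flags = c("fl", "bmi", "ratio", "tg")))
    dropped[r] <- "tg" %in% fit$selection$eliminated
  }
  expect_gte(mean(dropped), 0.90)
})

test_that("near-deterministic prior-status dynamics dominate the fit", {
  # status almost always persists; risk flags carry no signal
  withr::with_seed(42, {
    n <- 2000
    fl0 <- rbinom(n, 1, 0.4)
    fl1 <- ifelse(runif(n) < 0.98, fl0, 1L - fl0)
    df <- data.frame(
      person_id = rep(sprintf("D%05d", 1:n), each = 2),
      year = rep(c(2012L, 2013L), n),
      age = rep(45L, 2 * n) + rep(c(0L, 1L), n),
      fl = as.vector(rbind(fl0, fl1)),
      bmi = rep(sample(c(22, 28), n, TRUE), each = 2),
      ldl = rep(sample(c(90, 150), n, TRUE), each = 2),
      hdl = 60, tg = 100, sbp = 120, hba1c = 5.2,
      smoker = FALSE, drinker = FALSE, exerciser = FALSE, shiftwork = FALSE)
    pan <- as_cohort_panel(df)
  })
  fit <- fit_fl_transition(pan)
  expect_gt(fit$beta_fl, 5)
  expect_true(all(c("bmi", "ratio") %in% fit$selection$eliminated))
  expect_identical(fit$beta_bmi, 0)
})

test_that("transition fitting rejects inadequate or separated data", {
  truth <- fit_table_main_effects(ref_cells())
  small <- transitions_panel(30, truth, seed = 2)
  expect_error(fit_fl_transition(small), "at least 50")
  # perfectly deterministic persistence is complete separation
  fl_det <- matrix(rep(c(0L, 1L), each = 3), nrow = 60, ncol = 3,
                   byrow = FALSE)
  fl_det[1:30, ] <- 0L; fl_det[31:60, ] <- 1L
  pan <- tiny_panel(fl_det)
  expect_error(fit_fl_transition(pan, candidate_flags = "fl"), "separation")
})

test_that("covariate update fitting has exact and null behaviour", {
  # identity dynamics: slope 1, residual SD 0
  n <- 120
  df <- data.frame(
    person_id = rep(sprintf("U%04d", 1:n), each = 2),
    year = rep(c(2012L, 2013L), n),
    age = rep(40L, 2 * n) + rep(c(0L, 1L), n),
    fl = 0L, bmi = rep(seq(18, 32, length.out = n), each = 2),
    ldl = 110, hdl = 55, tg = 100, sbp = 120, hba1c = 5.3,
    smoker = FALSE, drinker = FALSE, exerciser = FALSE, shiftwork = FALSE)
  pan <- as_cohort_panel(df)
  fit <- fit_covariate_update(pan, "bmi", age_terms = FALSE)
  expect_equal(unname(fit$coef["slope"]), 1, tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-10)

  # permuted (t, t+1) pairing destroys the association: slope within 3 SE of 0
  withr::with_seed(9, {
    m <- 3000
    v0 <- rnorm(m, 23, 3)
    v1 <- sample(rnorm(m, 23, 3))
    dfp <- data.frame(
      person_id = rep(sprintf("Q%05d", 1:m), each = 2),
      year = rep(c(2012L, 2013L), m),
      age = rep(40L, 2 * m) + rep(c(0L, 1L), m),
      fl = 0L, bmi = as.vector(rbind(v0, v1)),
      ldl = 110, hdl = 55, tg = 100, sbp = 120, hba1c = 5.3,
      smoker = FALSE, drinker = FALSE, exerciser = FALSE, shiftwork = FALSE)
    panp <- as_cohort_panel(dfp)
  })
  fitp <- fit_covariate_update(panp, "bmi", age_terms = FALSE)
  se <- 1 / sqrt(m)   # slope SE ~ sd_resid / (sd_x * sqrt(n)) with sd ratio ~ 1
  expect_lt(abs(fitp$coef[["slope"]]), 3 * se)

  expect_error(fit_covariate_update(pan[1:20, ], "bmi"), "at least 50")
  expect_error(fit_covariate_update(pan, "height"), "must be one of")
})

test_that("imputation draws respect the model, the seed, and observed data", {
  truth <- fit_table_main_effects(ref_cells())
  pop <- generate_population(study_population_config(n_per_year = 1200,
                                                     years = 3, seed = 6))
  miss <- apply_missingness(pop, c("20-69" = 0.6), seed = 3)
  im <- fit_fl_imputation(miss)
  out1 <- impute_missing_fl(miss, im, seed = 10)
  out2 <- impute_missing_fl(miss, im, seed = 10)
  expect_identical(out1$fl, out2$fl)
  expect_false(anyNA(out1$fl))
  obs_idx <- which(!is.na(miss$fl))
  expect_identical(out1$fl[obs_idx], miss$fl[obs_idx])

  # missingness independent of covariates: imputed prevalence within 3
  # binomial SEs of the observed prevalence
  p_obs <- mean(miss$fl, na.rm = TRUE)
  n_miss <- sum(is.na(miss$fl))
  p_imp <- mean(out1$fl[is.na(miss$fl)])
  expect_lt(abs(p_imp - p_obs), 3 * sqrt(p_obs * (1 - p_obs) / n_miss) + 0.01)

  # intercept -> -Inf limit: every imputed status absent
  im0 <- im
  im0$coef[["(Intercept)"]] <- -50
  out0 <- impute_missing_fl(miss, im0, seed = 10)
  expect_true(all(out0$fl[is.na(miss$fl)] == 0L))
})
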