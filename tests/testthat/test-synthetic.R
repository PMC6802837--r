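test_that("generation is deterministic and satisfies panel invariants", {
  cfg <- study_population_config(n_per_year = 500, years = 4, seed = 33)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  expect_silent(validate_panel(p1))
  expect_equal(length(unique(p1$year)), 4L)
  # open enrollment: wave sizes drift upward at ~ +3%/yr
  sizes <- as.integer(table(p1$year))
  expect_true(all(diff(sizes) > 0))
})

test_that("the cohort-2 calibration hits its published marginals", {
  base <- baseline_state(generate_population(cohort2_config(seed = 1)))
  expect_equal(nrow(base), 2162L)
  expect_true(all(base$age >= 30 & base$age <= 39))
  expect_lt(abs(mean(base$bmi) - 23.3), 0.2)
  expect_lt(abs(mean(base$fl) - 0.198), 0.02)
  # BMI >= 25 fraction within exact binomial quantiles at the configured
  # category probability
  spec <- cohort2_config(seed = 1)$covariates$bmi
  mlog <- log(spec$mean - spec$shift) - log1p((spec$sd / (spec$mean - spec$shift))^2) / 2
  slog <- sqrt(log1p((spec$sd / (spec$mean - spec$shift))^2))
  p_cfg <- plnorm(25 - spec$shift, mlog, slog, lower.tail = FALSE)
  expect_lt(abs(p_cfg - 0.27), 0.005)   # shift was calibrated to 27.0%
  k <- sum(base$bmi >= 25)
  expect_gte(k, qbinom(5e-4, 2162, p_cfg))
  expect_lte(k, qbinom(1 - 5e-4, 2162, p_cfg))
  expect_lt(abs(k / 2162 - 0.27), 0.02)
})

test_that("a no-noise closed configuration freezes covariates and size", {
  specs <- list(
    bmi = covariate_spec(23, 3, rho = 1, resid_sd = 0),
    ldl = covariate_spec(120, 28, rho = 1, resid_sd = 0),
    hdl = covariate_spec(56, 13, rho = 1, resid_sd = 0),
    tg = covariate_spec(110, 80, shift = 0, rho = 1, resid_sd = 0),
    sbp = covariate_spec(122, 14, rho = 1, resid_sd = 0),
    hba1c = covariate_spec(5.4, 0.5, rho = 1, resid_sd = 0))
  cfg <- synthetic_config(n_per_year = 200, years = 3,
                          age_weights = c("30-39" = 1), covariates = specs,
                          enrollment_rate = 0, attrition_rate = 0, seed = 4)
  p <- generate_population(cfg)
  expect_equal(as.integer(table(p$year)), rep(200L, 3))
  for (v in c("bmi", "ldl", "hdl", "tg", "sbp", "hba1c")) {
    spread <- tapply(p[[v]], p$person_id, function(x) diff(range(x)))
    expect_true(all(spread < 1e-12))
  }
})

test_that("generated marginals converge to the configured moments", {
  # flat age profiles so the configured moments are the exact targets
  specs <- list(
    bmi = covariate_spec(23.3, 3.6, shift = 12, rho = 0.9),
    ldl = covariate_spec(118.5, 29.5, rho = 0.85),
    hdl = covariate_spec(56.6, 13.3, rho = 0.85),
    tg = covariate_spec(111, 83, shift = 0, rho = 0.7),
    sbp = covariate_spec(121, 14, rho = 0.7),
    hba1c = covariate_spec(5.2, 0.4, rho = 0.9))
  cfg <- synthetic_config(n_per_year = 50000, years = 1,
                          age_weights = c("30-39" = 1), covariates = specs,
                          seed = 8)
  p <- generate_population(cfg)
  n <- nrow(p)
  for (v in c("bmi", "ldl", "hdl", "sbp", "hba1c")) {
    s <- specs[[v]]
    expect_lt(abs(mean(p[[v]]) - s$mean), 3 * s$sd / sqrt(n))
    # SD standard error ~ sd / sqrt(2 n) for near-normal families
    expect_lt(abs(sd(p[[v]]) - s$sd), 4 * s$sd / sqrt(2 * n))
  }
  # configured negative LDL-HDL correlation is realized
  expect_lt(cor(p$ldl, p$hdl), -0.15)
  expect_gt(cor(p$ldl, p$hdl), -0.25)
})

test_that("invalid synthetic configurations are rejected with a message", {
  specs <- cohort2_config()$covariates
  expect_error(synthetic_config(100, 2, c("30-39" = 1), specs,
                                enrollment_rate = 1.2), "enrollment_rate")
  expect_error(synthetic_config(100, 2, c("30-39" = 1), specs,
                                attrition_rate = -0.1), "attrition_rate")
  expect_error(covariate_spec(23, -1), "sd")
  expect_error(covariate_spec(23, 3, resid_sd = -0.5), "resid_sd")
  expect_error(synthetic_config(100, 2, c(0.5, 0.5), specs), "named")
})

test_that("missingness is applied exactly per age band and only to status", {
  cfg <- synthetic_config(n_per_year = 3000, years = 1,
                          age_weights = c("20-29" = 1, "30-39" = 1,
                                          "40-69" = 1),
                          covariates = cohort2_config()$covariates, seed = 5)
  p <- generate_population(cfg)
  av <- c("20-29" = 0, "30-39" = 0.091, "40-69" = 0.955)
  pm <- apply_missingness(p, av, seed = 1)
  for (band in names(av)) {
    lim <- as.integer(strsplit(band, "-")[[1]])
    rows <- pm$age >= lim[1] & pm$age <= lim[2]
    expect_equal(sum(!is.na(pm$fl[rows])), round(av[[band]] * sum(rows)))
  }
  # everything except fl untouched
  expect_identical(pm$bmi, p$bmi)
  expect_identical(pm$person_id, p$person_id)
  # identity and all-missing limits
  expect_identical(apply_missingness(p, c("20-69" = 1))$fl, p$fl)
  expect_true(all(is.na(apply_missingness(p, c("20-69" = 0))$fl)))
  expect_error(apply_missingness(p, c("20-39" = 0.5)), "cover")
  expect_error(apply_missingness(p, c("20-69" = 1.5)), "availability")
})

test_that("cohort selection filters on first-wave age and completeness", {
  pop <- generate_population(study_population_config(n_per_year = 800,
                                                     years = 3, seed = 12))
  c2 <- select_cohort(pop, c(30, 39))
  first_ages <- tapply(c2$age, c2$person_id, min)
  expect_true(all(first_ages >= 30 & first_ages <= 39))
  # full range without completeness filter is the identity
  all_sel <- select_cohort(pop, c(20, 99))
  expect_equal(nrow(all_sel), nrow(pop))
  # exactly one person with one missing field is excluded, others kept
  fl3 <- matrix(0L, nrow = 5, ncol = 3)
  pan <- tiny_panel(fl3)
  pan$bmi[4] <- NA   # second wave of person 2
  cc <- select_cohort(pan, c(20, 99), complete_cases_only = TRUE)
  expect_setdiff <- setdiff(unique(pan$person_id), unique(cc$person_id))
  expect_identical(expect_setdiff, "P002")
  expect_warning(select_cohort(pop, c(95, 99)), "empty")
})
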