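#' Default synthetic calibrations
#'
#' Two ready-made [synthetic_config()]s emulating an occupational
#' health-examination population of adult Japanese men:
#'
#' * `study_population_config()` — the full study-population analogue:
#'   about 2000 men aged 20-69 per wave over five annual waves, open
#'   enrollment at 9%/yr and attrition at 6%/yr, marginals matching the
#'   published clinical/biochemical summary of such populations (BMI
#'   23.6 +/- 3.5 kg/m2, LDL-C 122.2 +/- 29.8 mg/dl, HDL-C 56.9 +/- 13.4
#'   mg/dl, TG 120.3 +/- 86.6 mg/dl, SBP 122.3 +/- 14.7 mmHg, HbA1c
#'   5.4 +/- 0.5%), and a baseline fatty-liver prevalence of 28%.
#'
#' * `cohort2_config()` — a single-wave cohort of 2162 men aged 30-39
#'   with the younger marginals of that age band (BMI 23.3 +/- 3.6,
#'   LDL-C 118.5 +/- 29.5, HDL-C 56.6 +/- 13.3, TG 111.3 +/- 82.9, SBP
#'   121.4 +/- 14.1, HbA1c 5.2 +/- 0.4) and a baseline fatty-liver
#'   prevalence of 19.8%; the BMI skew shift is calibrated so 27.0% of
#'   the cohort sits at or above 25 kg/m2.
#'
#' Both share the same age profiles (BMI rising about 0.05 kg/m2 per
#' year to a peak near 55 then declining, LDL-C rising to about age 50,
#' SBP and HbA1c rising monotonically) and the same true transition
#' model, the main-effects fit to the reference transition table.
#'
#' @param n_per_year,years,seed Overridable wave structure and seed.
#' @return A [synthetic_config()].
#' @export
study_population_config <- function(n_per_year = 2000, years = 5, seed = 1L) {
  synthetic_config(
    n_per_year = n_per_year, years = years,
    age_weights = c("20-29" = 0.10, "30-39" = 0.32, "40-49" = 0.33,
                    "50-59" = 0.20, "60-69" = 0.05),
    covariates = default_covariate_specs(
      bmi_mean = 23.6, bmi_sd = 3.5, bmi_flag_frac = 0.30,
      ldl_mean = 122.2, ldl_sd = 29.8, hdl_mean = 56.9, hdl_sd = 13.4,
      tg_mean = 120.3, tg_sd = 86.6, sbp_mean = 122.3, sbp_sd = 14.7,
      hba1c_mean = 5.4, hba1c_sd = 0.5, hba1c_hi_frac = 0.02),
    lifestyle = c(smoker = 0.33, drinker = 0.38, exerciser = 0.22,
                  shiftwork = 0.37),
    baseline_fl_prevalence = 0.28,
    seed = seed)
}

#' @rdname study_population_config
#' @export
cohort2_config <- function(n_per_year = 2162, years = 1, seed = 1L) {
  synthetic_config(
    n_per_year = n_per_year, years = years,
    age_weights = c("30-39" = 1),
    covariates = default_covariate_specs(
      bmi_mean = 23.3, bmi_sd = 3.6, bmi_flag_frac = 0.27,
      ldl_mean = 118.5, ldl_sd = 29.5, hdl_mean = 56.6, hdl_sd = 13.3,
      tg_mean = 111.3, tg_sd = 82.9, sbp_mean = 121.4, sbp_sd = 14.1,
      hba1c_mean = 5.2, hba1c_sd = 0.4, hba1c_hi_frac = 0.01),
    lifestyle = c(smoker = 0.354, drinker = 0.284, exerciser = 0.186,
                  shiftwork = 0.414),
    baseline_fl_prevalence = 0.198,
    seed = seed)
}

# Shared covariate generator specs: skewed families for BMI and TG,
# symmetric for the others, with the common age profiles.
default_covariate_specs <- function(bmi_mean, bmi_sd, bmi_flag_frac,
                                    ldl_mean, ldl_sd, hdl_mean, hdl_sd,
                                    tg_mean, tg_sd, sbp_mean, sbp_sd,
                                    hba1c_mean, hba1c_sd, hba1c_hi_frac) {
  list(
    bmi = covariate_spec(bmi_mean, bmi_sd,
                         shift = calibrate_skew_shift(bmi_mean, bmi_sd, 25,
                                                      bmi_flag_frac),
                         rho = 0.95, age_peak = 50,
                         slope_up = 0.06, slope_down = -0.08, lower = 12),
    ldl = covariate_spec(ldl_mean, ldl_sd, rho = 0.85, age_peak = 50,
                         slope_up = 0.6, slope_down = -0.15, lower = 30),
    hdl = covariate_spec(hdl_mean, hdl_sd, rho = 0.85, age_peak = 99,
                         slope_up = 0.15, lower = 10),
    tg = covariate_spec(tg_mean, tg_sd, shift = 0, rho = 0.7, age_peak = 55,
                        slope_up = 0.5, slope_down = -0.5, lower = 20),
    sbp = covariate_spec(sbp_mean, sbp_sd, rho = 0.7, age_peak = 99,
                         slope_up = 0.35, lower = 70),
    hba1c = covariate_spec(hba1c_mean, hba1c_sd,
                           shift = calibrate_skew_shift(hba1c_mean, hba1c_sd,
                                                        6.5, hba1c_hi_frac),
                           rho = 0.9, age_peak = 99,
                           slope_up = 0.012, lower = 3)
  )
}
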