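# Shared fixtures and independent oracles for the test suite.

# The published 8-cell transition surface used as calibration fixture.
ref_cells <- function() reference_transition_table()

# Main-effects coefficients implied by the published table (computed once
# by the log-odds least-squares oracle below and frozen).
true_betas <- c(beta0 = -3.4454800, beta_fl = 4.0610228,
                beta_bmi = 0.8927325, beta_ratio = 0.9211204)

# Independent least-squares oracle on the logit scale: explicit normal
# equations, no lm / lm.fit.
ls_logit_oracle <- function(cells) {
  X <- cbind(1, cells$fl, cells$bmi, cells$ratio)
  y <- log(cells$prob / (1 - cells$prob))
  solve(t(X) %*% X, t(X) %*% y)[, 1L]
}

# Long-run prevalence of the two-state chain by brute-force simulation.
chain_sim_oracle <- function(p01, p11, steps = 1e6, seed = 404) {
  withr::with_seed(seed, {
    u <- stats::runif(steps)
    x <- integer(steps)
    s <- 0L
    for (i in seq_len(steps)) {
      s <- if (s == 1L) as.integer(u[i] < p11) else as.integer(u[i] < p01)
      x[i] <- s
    }
    mean(x)
  })
}

# Hand-built tiny panel: n persons followed over `years` waves with
# constant covariates, explicit fatty-liver sequence per person.
tiny_panel <- function(fl_matrix, bmi = 22, ratio_hi = FALSE, start_age = 40) {
  n <- nrow(fl_matrix)
  years <- ncol(fl_matrix)
  hdl <- 60
  ldl <- if (ratio_hi) 150 else 90
  rows <- expand.grid(w = seq_len(years), i = seq_len(n))
  df <- data.frame(
    person_id = sprintf("P%03d", rows$i),
    year = 2011L + rows$w,
    age = start_age + rows$w - 1L,
    fl = fl_matrix[cbind(rows$i, rows$w)],
    bmi = bmi, ldl = ldl, hdl = hdl, tg = 100, sbp = 120, hba1c = 5.2,
    smoker = FALSE, drinker = FALSE, exerciser = FALSE, shiftwork = FALSE)
  as_cohort_panel(df, source = "fixture")
}

# Generate a person-transition panel directly from given transition-model
# coefficients and flag probabilities (bypasses the full generator).
transitions_panel <- function(n, model, p_bmi = 0.3, p_ratio = 0.5,
                              seed = 1, extra_null_flag = FALSE) {
  withr::with_seed(seed, {
    bmi_flag <- stats::rbinom(n, 1, p_bmi)
    ratio_flag <- stats::rbinom(n, 1, p_ratio)
    fl0 <- stats::rbinom(n, 1, 0.25)
    p <- transition_probability(model, fl0, bmi_flag, ratio_flag)
    fl1 <- stats::rbinom(n, 1, p)
    tg <- if (extra_null_flag) ifelse(stats::rbinom(n, 1, 0.3) == 1, 200, 100)
          else 100
    df <- data.frame(
      person_id = rep(sprintf("T%06d", seq_len(n)), each = 2),
      year = rep(c(2012L, 2013L), n),
      age = rep(40L, 2 * n) + rep(c(0L, 1L), n),
      fl = as.vector(rbind(fl0, fl1)),
      bmi = rep(ifelse(bmi_flag == 1, 28, 22), each = 2),
      ldl = rep(ifelse(ratio_flag == 1, 150, 90), each = 2),
      hdl = 60, tg = rep(tg, each = 2), sbp = 120, hba1c = 5.2,
      smoker = FALSE, drinker = FALSE, exerciser = FALSE, shiftwork = FALSE)
    as_cohort_panel(df, source = "fixture")
  })
}

# Frozen-covariate member table sitting in one transition-table cell.
frozen_members <- function(n, fl, bmi_flag, ratio_flag) {
  data.frame(age = rep(40L, n), fl = rep(as.integer(fl), n),
             bmi = if (bmi_flag) 30 else 20,
             ratio = if (ratio_flag) 3 else 1)
}

# Identity update models (slope 1, no age effect, no noise).
identity_updates <- function(sigma = 0) {
  list(bmi = covariate_update_model("bmi", c(intercept = 0, slope = 1), sigma),
       ratio = covariate_update_model("ratio", c(intercept = 0, slope = 1),
                                      sigma))
}
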