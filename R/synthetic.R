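#' Specification of one synthetic risk-factor generator
#'
#' Each continuous risk factor is generated from a location/scale family
#' (symmetric normal, or a shifted log-normal when the marginal must be
#' right-skewed) around a piecewise-linear age profile, and evolved across
#' waves by a mean-reverting first-order autoregression:
#'
#' \deqn{V_{t+1} = \mu(a+1) + \rho\,(V_t - \mu(a)) + \epsilon}
#'
#' where `mu(a)` is the age profile and `epsilon ~ N(0, resid_sd)`.  With
#' the default `resid_sd = sd * sqrt(1 - rho^2)` the marginal SD is
#' preserved along the age profile.
#'
#' The skew matters: a BMI marginal with mean 23.3 and SD 3.6 kg/m2 must
#' coexist with roughly 27% of the population at or above 25 kg/m2, which
#' a symmetric normal cannot deliver (it gives about 32%); a shifted
#' log-normal reconciles the two.  Use [calibrate_skew_shift()] to find
#' the shift hitting a target category fraction.
#'
#' @param mean,sd Marginal mean and SD at the reference age.
#' @param shift Log-normal location shift (support is `(shift, Inf)`);
#'   `NA` for a symmetric normal.
#' @param rho Autoregressive persistence in \[0, 1\] (`rho = 1` with
#'   `resid_sd = 0` gives frozen identity dynamics).
#' @param resid_sd Residual SD of the annual update; default
#'   `sd * sqrt(1 - rho^2)`.
#' @param age_peak,slope_up,slope_down Piecewise-linear age profile: the
#'   expected value rises by `slope_up` per year up to `age_peak` and
#'   changes by `slope_down` per year beyond it.
#' @param lower Physiologic lower bound enforced on generated values.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(mean, sd, shift = NA, rho = 0.9, resid_sd = NULL,
                           age_peak = 99, slope_up = 0, slope_down = 0,
                           lower = 1) {
  if (sd <= 0) stopf("sd must be positive")
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  if (is.null(resid_sd)) resid_sd <- sd * sqrt(1 - rho^2)
  if (resid_sd < 0) stopf("resid_sd must be non-negative")
  if (!is.na(shift) && shift >= mean)
    stopf("shift must be below the mean")
  structure(list(mean = mean, sd = sd, shift = shift, rho = rho,
                 resid_sd = resid_sd, age_peak = age_peak,
                 slope_up = slope_up, slope_down = slope_down, lower = lower),
            class = "covariate_spec")
}

# Piecewise-linear age profile relative to the reference age.
profile_delta <- function(spec, age, ref_age) {
  q <- function(a) spec$slope_up * (pmin(a, spec$age_peak) - spec$age_peak) +
                   spec$slope_down * (pmax(a, spec$age_peak) - spec$age_peak)
  q(age) - q(ref_age)
}

# Shifted log-normal parameters for mean/sd above the shift.
sl_params <- function(mean, sd, shift) {
  m2 <- mean - shift
  cv <- sd / m2
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(m2) - sdlog^2 / 2, sdlog = sdlog)
}

# Zero-mean draw from a covariate_spec's marginal family.
draw_centered <- function(n, spec) {
  if (is.na(spec$shift)) return(stats::rnorm(n, 0, spec$sd))
  p <- sl_params(spec$mean, spec$sd, spec$shift)
  spec$shift + stats::rlnorm(n, p$meanlog, p$sdlog) - spec$mean
}

#' Calibrate the log-normal shift to a target category fraction
#'
#' Finds the shift such that a shifted log-normal with the given mean and
#' SD has `P(X >= threshold) = target`.  The target must be below the
#' symmetric-normal fraction (more shift means more right skew, which
#' moves mass below an above-mean threshold).
#'
#' @param mean,sd Marginal moments.
#' @param threshold Category cut-point.
#' @param target Target fraction at or above the threshold.
#' @return The calibrated shift (numeric).
#' @export
calibrate_skew_shift <- function(mean, sd, threshold, target) {
  check_fraction(target, "target")
  frac_at <- function(shift) {
    p <- sl_params(mean, sd, shift)
    stats::plnorm(threshold - shift, p$meanlog, p$sdlog, lower.tail = FALSE)
  }
  # the fraction is not monotone in the shift for far-tail thresholds, so
  # bracket on a grid and take the least-skew (smallest-shift) crossing
  grid <- mean - sd * exp(seq(log(60), log(0.15), length.out = 400))
  f <- vapply(grid, frac_at, numeric(1)) - target
  cross <- which(f[-1L] * f[-length(f)] <= 0)
  if (!length(cross))
    stopf("target fraction %.3f not attainable with mean %.3g, sd %.3g at threshold %.3g",
          target, mean, sd, threshold)
  k <- cross[1L]
  stats::uniroot(function(s) frac_at(s) - target, c(grid[k], grid[k + 1L]),
                 tol = 1e-8)$root
}

#' Synthetic cohort configuration
#'
#' Bundles everything [generate_population()] needs: wave structure, age
#' mix, per-variable generators, the true transition model driving the
#' fatty-liver state, open-enrollment dynamics and the RNG seed.
#'
#' @param n_per_year Persons in the first wave.
#' @param years Number of annual waves.
#' @param age_weights Named per-decade weights, names like `"30-39"`.
#' @param covariates Named list of [covariate_spec()]s for `bmi`, `ldl`,
#'   `hdl`, `tg`, `sbp`, `hba1c`.
#' @param ldl_hdl_cor Correlation between LDL-C and HDL-C draws (baseline
#'   and residuals); slightly negative in examination data, default -0.2.
#' @param lifestyle Named prevalences of `smoker`, `drinker`, `exerciser`,
#'   `shiftwork`; booleans are drawn once per person and held fixed.
#' @param fl_model The true [fl_transition_model()] evolving status; the
#'   baseline status is one Bernoulli draw from a logistic in the
#'   dichotomized covariates whose slopes are the main-effects fit to the
#'   per-cell stationary log-odds of `fl_model` and whose intercept is
#'   calibrated so the first-wave prevalence matches
#'   `baseline_fl_prevalence`.
#' @param baseline_fl_prevalence Target first-wave prevalence (`NULL` for
#'   the uncalibrated stationary level).
#' @param enrollment_rate,attrition_rate Annual open-population rates
#'   (defaults 0.09 in, 0.06 out).
#' @param retire_age Members leave the programme after this age (default
#'   69, the upper examination age of an occupational population).
#' @param thresholds A [risk_thresholds()].
#' @param start_year First calendar year (default 2012).
#' @param seed RNG seed; identical configurations generate byte-identical
#'   panels.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_year, years, age_weights, covariates,
                             ldl_hdl_cor = -0.2,
                             lifestyle = c(smoker = 0.33, drinker = 0.38,
                                           exerciser = 0.22, shiftwork = 0.37),
                             fl_model = fit_table_main_effects(reference_transition_table()),
                             baseline_fl_prevalence = NULL,
                             enrollment_rate = 0.09, attrition_rate = 0.06,
                             retire_age = 69L, thresholds = risk_thresholds(),
                             start_year = 2012L, seed = 1L) {
  if (n_per_year < 1 || years < 1) stopf("n_per_year and years must be >= 1")
  check_fraction(enrollment_rate, "enrollment_rate")
  check_fraction(attrition_rate, "attrition_rate")
  if (!is.null(baseline_fl_prevalence))
    check_fraction(baseline_fl_prevalence, "baseline_fl_prevalence")
  if (!is.numeric(age_weights) || is.null(names(age_weights)) ||
      any(age_weights < 0) || sum(age_weights) <= 0)
    stopf("age_weights must be named non-negative weights with positive sum")
  need <- continuous_vars()
  if (!all(need %in% names(covariates)))
    stopf("covariates must contain specs for: %s", paste(need, collapse = ", "))
  for (v in need)
    if (!inherits(covariates[[v]], "covariate_spec"))
      stopf("covariates$%s is not a covariate_spec", v)
  if (abs(ldl_hdl_cor) >= 1) stopf("ldl_hdl_cor must lie in (-1, 1)")
  if (!all(lifestyle_vars() %in% names(lifestyle)))
    stopf("lifestyle must name: %s", paste(lifestyle_vars(), collapse = ", "))
  check_fraction(lifestyle, "lifestyle")
  stopifnot(inherits(fl_model, "fl_transition_model"))
  bands <- parse_bands(names(age_weights))
  if (retire_age < max(bands$hi))
    stopf("retire_age must not be below the oldest age band")
  mids <- (bands$lo + bands$hi) / 2
  structure(list(n_per_year = as.integer(n_per_year), years = as.integer(years),
                 age_weights = age_weights / sum(age_weights),
                 covariates = covariates[need], ldl_hdl_cor = ldl_hdl_cor,
                 lifestyle = lifestyle[lifestyle_vars()], fl_model = fl_model,
                 baseline_fl_prevalence = baseline_fl_prevalence,
                 enrollment_rate = enrollment_rate,
                 attrition_rate = attrition_rate,
                 retire_age = as.integer(retire_age), thresholds = thresholds,
                 start_year = as.integer(start_year), seed = as.integer(seed),
                 ref_age = sum(mids * age_weights / sum(age_weights))),
            class = "synthetic_config")
}

parse_bands <- function(labels) {
  m <- regmatches(labels, regexec("^([0-9]+)-([0-9]+)$", labels))
  if (any(vapply(m, length, integer(1)) != 3L))
    stopf("age band labels must look like '30-39'")
  lo <- vapply(m, function(x) as.integer(x[2L]), integer(1))
  hi <- vapply(m, function(x) as.integer(x[3L]), integer(1))
  if (any(lo > hi)) stopf("age band lower bound exceeds upper bound")
  data.frame(label = labels, lo = lo, hi = hi)
}

# Main-effects logistic surface for the per-cell stationary prevalence of
# the two-state chain induced by a transition model.
stationary_logit_coefs <- function(fl_model) {
  tab <- build_table(fl_model)
  p01 <- tab$prob[tab$fl == 0]
  p11 <- tab$prob[tab$fl == 1]
  ps <- stationary_prevalence(p01, p11)
  X <- cbind(1, tab$bmi[tab$fl == 0], tab$ratio[tab$fl == 0])
  stats::setNames(stats::lm.fit(X, stats::qlogis(ps))$coefficients,
                  c("intercept", "bmi", "ratio"))
}

draw_ages <- function(n, config) {
  bands <- parse_bands(names(config$age_weights))
  k <- sample.int(nrow(bands), n, replace = TRUE, prob = config$age_weights)
  bands$lo[k] + floor(stats::runif(n) * (bands$hi[k] - bands$lo[k] + 1L))
}

# Baseline covariate draws for persons of the given ages.
draw_covariates <- function(ages, config) {
  n <- length(ages)
  cov <- config$covariates
  out <- data.frame(row.names = seq_len(n))
  # correlated normal pair for the lipids
  r <- config$ldl_hdl_cor
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  for (v in continuous_vars()) {
    s <- cov[[v]]
    mu <- s$mean + profile_delta(s, ages, config$ref_age)
    x <- switch(v,
      ldl = mu + s$sd * z1,
      hdl = mu + s$sd * z2,
      mu + draw_centered(n, s))
    out[[v]] <- pmax(x, s$lower)
  }
  out
}

draw_baseline_fl <- function(cov, config, offset) {
  fx <- risk_flags(cov, config$thresholds)
  b <- stationary_logit_coefs(config$fl_model)
  eta <- b["intercept"] + b["bmi"] * as.numeric(fx$bmi) +
         b["ratio"] * as.numeric(fx$ratio) + offset
  stats::rbinom(nrow(cov), 1L, stats::plogis(eta))
}

calibrate_fl_offset <- function(cov, config) {
  if (is.null(config$baseline_fl_prevalence)) return(0)
  fx <- risk_flags(cov, config$thresholds)
  b <- stationary_logit_coefs(config$fl_model)
  eta <- b["intercept"] + b["bmi"] * as.numeric(fx$bmi) +
         b["ratio"] * as.numeric(fx$ratio)
  target <- config$baseline_fl_prevalence
  stats::uniroot(function(o) mean(stats::plogis(eta + o)) - target,
                 c(-15, 15), tol = 1e-9)$root
}

draw_lifestyle <- function(n, config) {
  out <- data.frame(row.names = seq_len(n))
  for (v in lifestyle_vars())
    out[[v]] <- stats::runif(n) < config$lifestyle[[v]]
  out
}

# One annual covariate update for the generator's state table.
update_covariates <- function(state, config) {
  n <- nrow(state)
  cov <- config$covariates
  r <- config$ldl_hdl_cor
  e1 <- stats::rnorm(n)
  e2 <- r * e1 + sqrt(1 - r^2) * stats::rnorm(n)
  for (v in continuous_vars()) {
    s <- cov[[v]]
    mu0 <- s$mean + profile_delta(s, state$age, config$ref_age)
    mu1 <- s$mean + profile_delta(s, state$age + 1L, config$ref_age)
    e <- switch(v, ldl = s$resid_sd * e1, hdl = s$resid_sd * e2,
                stats::rnorm(n, 0, s$resid_sd))
    state[[v]] <- pmax(mu1 + s$rho * (state[[v]] - mu0) + e, s$lower)
  }
  state
}

#' Generate a synthetic longitudinal health-examination panel
#'
#' Simulates `config$years` annual waves of an open employee population:
#' covariates evolve by their configured autoregressions around
#' piecewise-linear age profiles, fatty-liver status evolves by the
#' configured transition model applied to the dichotomized covariates
#' before transition, a fraction `attrition_rate` of members leaves each
#' year and `enrollment_rate` enters.  Deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @return A `cohort_panel` with fully observed fatty-liver status (apply
#'   [apply_missingness()] to emulate age-dependent availability).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n0 <- config$n_per_year
    max_age <- config$retire_age
    ages <- draw_ages(n0, config)
    cov <- draw_covariates(ages, config)
    offset <- calibrate_fl_offset(cov, config)
    state <- cbind(data.frame(person_id = sprintf("S%06d", seq_len(n0)),
                              age = as.integer(ages),
                              fl = draw_baseline_fl(cov, config, offset)),
                   cov, draw_lifestyle(n0, config))
    next_id <- n0 + 1L
    waves <- vector("list", config$years)
    for (t in seq_len(config$years)) {
      waves[[t]] <- cbind(state["person_id"],
                          data.frame(year = config$start_year + t - 1L),
                          state[setdiff(names(state), "person_id")])
      if (t == config$years) break
      n_t <- nrow(state)
      # attrition
      keep <- stats::runif(n_t) >= config$attrition_rate
      state <- state[keep, , drop = FALSE]
      # transition of fatty liver from pre-update flags, then the updates
      fx <- risk_flags(state, config$thresholds)
      p <- transition_probability(config$fl_model, state$fl,
                                  as.numeric(fx$bmi), as.numeric(fx$ratio))
      state$fl <- stats::rbinom(nrow(state), 1L, p)
      state <- update_covariates(state, config)
      state$age <- state$age + 1L
      # retirement: members aging out of the examination programme leave
      state <- state[state$age <= max_age, , drop = FALSE]
      # enrollment, relative to the pre-attrition wave size
      m <- round(n_t * config$enrollment_rate)
      if (m > 0) {
        ages_new <- draw_ages(m, config)
        cov_new <- draw_covariates(ages_new, config)
        entrants <- cbind(data.frame(person_id = sprintf("S%06d", next_id + seq_len(m) - 1L),
                                     age = as.integer(ages_new),
                                     fl = draw_baseline_fl(cov_new, config, offset)),
                          cov_new, draw_lifestyle(m, config))
        next_id <- next_id + m
        state <- rbind(state, entrants)
      }
      rownames(state) <- NULL
    }
    panel <- do.call(rbind, waves)
    panel <- panel[c("person_id", "year", "age", "fl", continuous_vars(),
                     lifestyle_vars())]
    as_cohort_panel(panel, source = "synthetic")
  })
}

#' Blank out fatty-liver status by age-band availability
#'
#' Emulates the age-dependent availability of the ultrasonography
#' diagnosis in the examination programme: within each age band a seeded
#' random subset of records keeps its observed status so that the
#' realized per-band availability matches the target fraction exactly (to
#' rounding); all other fields are untouched.
#'
#' @param panel A `cohort_panel`.
#' @param availability Named fractions in \[0, 1\], names like `"40-69"`;
#'   the bands must cover every age in the panel.  Default: 0% at 20-29,
#'   9.1% at 30-39, 95.5% at 40-69.
#' @param seed Integer seed for the subset draw.
#' @return The panel with `fl` set to `NA` outside the retained subsets.
#' @export
apply_missingness <- function(panel,
                              availability = c("20-29" = 0, "30-39" = 0.091,
                                               "40-69" = 0.955),
                              seed = 1L) {
  check_fraction(availability, "availability")
  bands <- parse_bands(names(availability))
  band_of <- rep(NA_integer_, nrow(panel))
  for (k in seq_len(nrow(bands)))
    band_of[panel$age >= bands$lo[k] & panel$age <= bands$hi[k]] <- k
  if (anyNA(band_of))
    stopf("availability bands do not cover panel age %d",
          panel$age[which(is.na(band_of))[1L]])
  with_seed(seed, {
    for (k in seq_len(nrow(bands))) {
      idx <- which(band_of == k)
      n_miss <- round((1 - availability[[k]]) * length(idx))
      if (n_miss > 0)
        panel$fl[sample(idx, n_miss)] <- NA_integer_
    }
  })
  panel
}

#' Select a theoretical cohort from a panel
#'
#' Keeps the members whose age at their first observed wave falls in
#' `age_range`; optionally restricts to complete cases — members present
#' in every observation year with no missing field in any wave — the
#' construction used for model calibration cohorts.
#'
#' @param panel A `cohort_panel`.
#' @param age_range Length-2 integer vector `c(lo, hi)`, inclusive.
#' @param complete_cases_only Keep only members observed in all panel
#'   years with no missing field in any wave (default `FALSE`).
#' @return A `cohort_panel` with all waves of the selected members; an
#'   empty selection returns an empty panel with a warning.
#' @export
select_cohort <- function(panel, age_range, complete_cases_only = FALSE) {
  if (length(age_range) != 2L || age_range[1L] > age_range[2L])
    stopf("age_range must be c(lo, hi) with lo <= hi")
  p <- as.data.frame(panel)
  o <- order(p$person_id, p$year)
  first <- p[o, ][!duplicated(p$person_id[o]), ]
  keep_ids <- first$person_id[first$age >= age_range[1L] &
                              first$age <= age_range[2L]]
  if (complete_cases_only) {
    cc <- stats::complete.cases(p[c("fl", continuous_vars(), lifestyle_vars())])
    bad_ids <- unique(p$person_id[!cc])
    keep_ids <- setdiff(keep_ids, bad_ids)
    n_years <- length(unique(p$year))
    waves_per_id <- table(p$person_id)
    keep_ids <- keep_ids[waves_per_id[keep_ids] == n_years]
  }
  out <- p[p$person_id %in% keep_ids, ]
  if (!nrow(out)) warning("cohort selection is empty")
  src <- attr(panel, "meta")$source
  as_cohort_panel(out, source = sprintf("%s[%d-%d]",
                                        if (is.null(src)) "panel" else src,
                                        age_range[1L], age_range[2L]))
}
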