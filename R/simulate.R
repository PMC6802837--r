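#' Monte Carlo simulation configuration
#'
#' @param n_runs Number of replicate projections (default 10); the
#'   mean and SD across runs define the central trajectory and the
#'   +/- 2 SD Monte Carlo band.
#' @param horizon Projection length in years, or `NULL` to project until
#'   the cohort's mean age reaches the 70-79 band (its upper edge, so the
#'   whole band is traversed).
#' @param seed Base RNG seed; run `r` uses a child seed derived from
#'   `seed` and `r`, so two simulations with the same seed share random
#'   numbers run-by-run (common random numbers for paired contrasts).
#' @param perturbation Named multiplicative modifiers of the annual
#'   covariate-update predictions, e.g. `c(bmi = 1.01)` for a +1% change
#'   in every annual BMI update; all values must be positive.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_runs = 10L, horizon = NULL, seed = 1L,
                              perturbation = c(bmi = 1, ratio = 1)) {
  if (n_runs < 1) stopf("n_runs must be >= 1")
  if (!is.null(horizon) && horizon < 1) stopf("horizon must be >= 1")
  if (any(perturbation <= 0)) stopf("perturbation multipliers must be positive")
  structure(list(n_runs = as.integer(n_runs),
                 horizon = if (is.null(horizon)) NULL else as.integer(horizon),
                 seed = as.integer(seed), perturbation = perturbation,
                 closed_population = TRUE),
            class = "simulation_config")
}

# Physiologic bounds enforced on simulated covariates (resampling by
# inverse-CDF truncation, so RNG use stays paired across arms).
sim_bounds <- function(variable) {
  switch(variable, bmi = c(12, 60), ratio = c(0.05, 10), c(-Inf, Inf))
}

#' Advance a member table by one simulated year
#'
#' For each member: (1) the fatty-liver status for next year is drawn
#' Bernoulli at the transition probability given the *current* (before
#' transition) status and risk flags; (2) each modelled covariate is
#' updated to its [predict_update()] prediction times the perturbation
#' multiplier plus a truncated-Gaussian residual with the model's fitted
#' SD; (3) age advances by one.  Lifestyle booleans and covariates
#' without an update model are carried forward unchanged.
#'
#' @param members Data frame with columns `age`, `fl` and one column per
#'   updated variable (at least `bmi` and `ratio`).
#' @param fl_model An [fl_transition_model()].
#' @param update_models Named list of [covariate_update_model()]s; must
#'   cover `bmi` and `ratio`.
#' @param perturbation Named multipliers (see [simulation_config()]).
#' @param thresholds A [risk_thresholds()].
#' @return The advanced member table.  Uses the current RNG stream;
#'   [simulate_lifecourse()] seeds it per run.
#' @export
simulate_year <- function(members, fl_model, update_models,
                          perturbation = c(bmi = 1, ratio = 1),
                          thresholds = risk_thresholds()) {
  need <- c("bmi", "ratio")
  missing_models <- setdiff(need, names(update_models))
  if (length(missing_models))
    stopf("missing update model(s) for: %s", paste(missing_models, collapse = ", "))
  if (anyNA(members$fl)) stopf("every member needs a current fatty-liver status")
  n <- nrow(members)
  bmi_flag <- as.numeric(members$bmi >= thresholds$bmi_hi)
  ratio_flag <- as.numeric(members$ratio >= thresholds$ratio_hi)
  p <- transition_probability(fl_model, members$fl, bmi_flag, ratio_flag)
  fl_next <- stats::rbinom(n, 1L, p)
  for (v in names(update_models)) {
    m <- update_models[[v]]
    mult <- if (v %in% names(perturbation)) perturbation[[v]] else 1
    pred <- predict_update(m, members[[v]], members$age) * mult
    b <- sim_bounds(v)
    members[[v]] <- if (m$log) {
      exp(rtruncnorm_inv(n, log(pred), rep(m$sigma, n), log(b[1L]), log(b[2L])))
    } else {
      rtruncnorm_inv(n, pred, rep(m$sigma, n), b[1L], b[2L])
    }
  }
  members$fl <- fl_next
  members$age <- members$age + 1L
  members
}

#' Project a cohort's fatty-liver life-course by Monte Carlo
#'
#' Runs `config$n_runs` independent replicate projections of every cohort
#' member from the same baseline, recording at each projection year the
#' prevalence of fatty liver, of BMI >= 25 kg/m2 and of LDL-C/HDL-C >= 2,
#' and the cohort mean age.  The across-run mean and SD at each year give
#' the central trajectory and its Monte Carlo variation; the population
#' is closed (no entry, exit or death).
#'
#' @param cohort A `cohort_panel` (its first observed wave per member,
#'   with status present or imputed, is the baseline) or a member table
#'   from [baseline_state()].
#' @param fl_model An [fl_transition_model()].
#' @param update_models Named list of [covariate_update_model()]s.
#' @param config A [simulation_config()].
#' @param thresholds A [risk_thresholds()].
#' @return An `fl_trajectory` data frame: one row per projection step
#'   (step 0 = baseline) with `mean_age`, and `<q>_mean`, `<q>_sd` for
#'   `q` in `fl`, `bmi`, `ratio`.  Deterministic given `config$seed`.
#' @export
simulate_lifecourse <- function(cohort, fl_model, update_models,
                                config = simulation_config(),
                                thresholds = risk_thresholds()) {
  base <- if (inherits(cohort, "cohort_panel")) baseline_state(cohort)
          else as.data.frame(cohort)
  if (!nrow(base)) stopf("empty cohort")
  if (!"ratio" %in% names(base)) base$ratio <- ldl_hdl_ratio(base$ldl, base$hdl)
  horizon <- config$horizon
  if (is.null(horizon))
    horizon <- max(1L, as.integer(ceiling(79 - mean(base$age))))
  keep <- intersect(c("age", "fl", "bmi", "ratio"), names(base))
  base <- base[keep]
  n <- nrow(base)
  q_names <- c("fl", "bmi", "ratio")
  arr <- array(NA_real_, dim = c(config$n_runs, horizon + 1L, length(q_names) + 1L))
  snapshot <- function(mem) c(mean(mem$fl),
                              mean(mem$bmi >= thresholds$bmi_hi),
                              mean(mem$ratio >= thresholds$ratio_hi),
                              mean(mem$age))
  for (r in seq_len(config$n_runs)) {
    arr[r, 1L, ] <- snapshot(base)
    with_seed(derive_seed(config$seed, r), {
      mem <- base
      for (t in seq_len(horizon)) {
        mem <- simulate_year(mem, fl_model, update_models,
                             perturbation = config$perturbation,
                             thresholds = thresholds)
        arr[r, t + 1L, ] <- snapshot(mem)
      }
    })
  }
  out <- data.frame(step = 0:horizon,
                    mean_age = apply(arr[, , 4L, drop = FALSE], 2L, mean))
  for (k in seq_along(q_names)) {
    out[[paste0(q_names[k], "_mean")]] <- apply(arr[, , k, drop = FALSE], 2L, mean)
    out[[paste0(q_names[k], "_sd")]] <-
      if (config$n_runs > 1L) apply(arr[, , k, drop = FALSE], 2L, stats::sd)
      else rep(0, horizon + 1L)
  }
  structure(out, class = c("fl_trajectory", "data.frame"),
            n_members = n, n_runs = config$n_runs, seed = config$seed,
            perturbation = config$perturbation)
}

#' @export
print.fl_trajectory <- function(x, ...) {
  cat(sprintf("<fl_trajectory> %d members, %d runs, %d projection years; FL %.1f%% -> peak %.1f%% -> %.1f%%\n",
              attr(x, "n_members"), attr(x, "n_runs"), max(x$step),
              100 * x$fl_mean[1L], 100 * max(x$fl_mean),
              100 * x$fl_mean[nrow(x)]))
  invisible(x)
}

#' Check observed prevalences against the Monte Carlo band
#'
#' A year is covered when the observed prevalence lies within +/- 2 SD of
#' the simulated mean, the criterion used for model calibration.
#'
#' @param traj An `fl_trajectory`.
#' @param observed Data frame with columns `step` and `value` (observed
#'   prevalence per projection step present in `traj`).
#' @param quantity `"fl"`, `"bmi"` or `"ratio"`.
#' @return Logical vector, one element per observed year.
#' @export
band_coverage <- function(traj, observed, quantity = "fl") {
  if (!quantity %in% c("fl", "bmi", "ratio")) stopf("unknown quantity '%s'", quantity)
  if (!all(c("step", "value") %in% names(observed)))
    stopf("observed must have columns 'step' and 'value'")
  idx <- match(observed$step, traj$step)
  if (anyNA(idx))
    stopf("observed step(s) not in trajectory: %s",
          paste(observed$step[is.na(idx)], collapse = ", "))
  m <- traj[[paste0(quantity, "_mean")]][idx]
  s <- traj[[paste0(quantity, "_sd")]][idx]
  abs(observed$value - m) <= 2 * s
}

#' Plot a projected life-course with its Monte Carlo band
#'
#' @param x An `fl_trajectory`.
#' @param quantity `"fl"`, `"bmi"` or `"ratio"`.
#' @param observed Optional data frame with `step` and `value` points.
#' @param ... Unused.
#' @return A ggplot object (prevalence vs cohort mean age, ribbon at
#'   +/- 2 SD).
#' @export
plot.fl_trajectory <- function(x, quantity = "fl", observed = NULL, ...) {
  m <- x[[paste0(quantity, "_mean")]]
  s <- x[[paste0(quantity, "_sd")]]
  df <- data.frame(age = x$mean_age, y = m, lo = pmax(m - 2 * s, 0),
                   hi = pmin(m + 2 * s, 1))
  lab <- c(fl = "Fatty liver", bmi = "BMI >= 25 kg/m2",
           ratio = "LDL-C/HDL-C >= 2")[[quantity]]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = age, y = y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), fill = "grey80") +
    ggplot2::geom_line(color = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "Cohort mean age (years)",
                  y = sprintf("Prevalence of %s", lab)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    idx <- match(observed$step, x$step)
    gg <- gg + ggplot2::geom_point(
      data = data.frame(age = x$mean_age[idx], y = observed$value),
      color = "red3")
  }
  gg
}
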