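#' Vary the initial composition of a cohort
#'
#' Builds a theoretical cohort whose baseline prevalence of one risk
#' category equals `(1 + factor)` times the original, by stratified
#' resampling with replacement (separately within the abnormal and normal
#' strata), leaving the cohort size unchanged.  All other marginals are
#' disturbed only through the resampling.  With `factor = 0` the input
#' cohort is returned unchanged.
#'
#' @param cohort A `cohort_panel`.
#' @param flag Category to vary: one of `"bmi"`, `"ldl"`, `"hdl"`,
#'   `"ratio"`, `"tg"`, `"sbp"`, `"hba1c"`, `"smoker"`, `"drinker"`,
#'   `"exerciser"`, `"shiftwork"` (abnormality at baseline for the
#'   continuous axes, the boolean itself for lifestyle axes).
#' @param factor Relative change in \[-0.9, 0.9\]; the implied target
#'   prevalence must stay inside (0, 1).
#' @param seed Integer seed for the resampling.
#' @param thresholds A [risk_thresholds()].
#' @return A `cohort_panel` of resampled members (re-identified so panel
#'   invariants hold).
#' @export
vary_initial <- function(cohort, flag, factor, seed = 1L,
                         thresholds = risk_thresholds()) {
  axes <- c("bmi", "ldl", "hdl", "ratio", "tg", "sbp", "hba1c",
            lifestyle_vars())
  if (!flag %in% axes) stopf("unknown axis '%s'", flag)
  if (abs(factor) > 0.9) stopf("factor must lie in [-0.9, 0.9]")
  if (factor == 0) return(cohort)
  base <- baseline_state(cohort, require_fl = FALSE)
  is_ab <- if (flag %in% lifestyle_vars()) base[[flag]]
           else risk_flags(base, thresholds)[[flag]]
  p0 <- mean(is_ab)
  target <- (1 + factor) * p0
  if (target <= 0 || target >= 1)
    stopf("target prevalence %.3f outside (0, 1)", target)
  n <- nrow(base)
  k <- round(target * n)
  ab_ids <- base$person_id[is_ab]
  no_ids <- base$person_id[!is_ab]
  if (!length(ab_ids) || !length(no_ids))
    stopf("cannot resample: a stratum is empty")
  picked <- with_seed(seed, c(
    sample(ab_ids, k, replace = TRUE),
    sample(no_ids, n - k, replace = TRUE)))
  p <- as.data.frame(cohort)
  byid <- split(seq_len(nrow(p)), p$person_id)
  idx_list <- byid[picked]
  out <- p[unlist(idx_list, use.names = FALSE), , drop = FALSE]
  out$person_id <- rep(sprintf("R%06d", seq_along(picked)), lengths(idx_list))
  as_cohort_panel(out, source = sprintf("resampled(%s%+.0f%%)", flag,
                                        100 * factor))
}

sens_changes <- function(traj_base, traj_alt) {
  # percentage-point differences in fatty-liver prevalence, aligned on step
  h <- min(nrow(traj_base), nrow(traj_alt))
  d <- 100 * (traj_alt$fl_mean[seq_len(h)] - traj_base$fl_mean[seq_len(h)])
  age <- traj_base$mean_age[seq_len(h)]
  in_band <- age >= 50 & age < 60
  band <- 10 * floor(age / 10)
  band_means <- tapply(d, band, mean)
  list(change_50s = if (any(in_band)) mean(d[in_band]) else NA_real_,
       max_abs_change = max(abs(d)),
       max_abs_band = max(abs(band_means)),
       change_start = mean(d[seq_len(min(6L, h))]),
       change_final = mean(d[seq.int(max(1L, h - 4L), h)]),
       diff = d)
}

sens_row <- function(axis, factor, ch) {
  data.frame(axis = axis, factor = factor, change_50s = ch$change_50s,
             max_abs_change = ch$max_abs_change,
             max_abs_band = ch$max_abs_band,
             change_start = ch$change_start, change_final = ch$change_final)
}

#' One-way sensitivity to initial cohort composition (S-1)
#'
#' For each axis and variation factor, resamples the cohort with
#' [vary_initial()], projects it with the same simulation seed as the
#' unvaried baseline (common random numbers), and records the change in
#' fatty-liver prevalence: while the cohort mean age is in the 50-59
#' band, and the maximum absolute change over the projection.
#'
#' @param cohort A `cohort_panel`.
#' @param fl_model,update_models,config,thresholds As in
#'   [simulate_lifecourse()].
#' @param axes Axes to vary (see [vary_initial()]).
#' @param factors Variation factors (default +/-20% and +/-40%).
#' @return A `sensitivity_result` data frame (all in percentage points):
#'   `axis`, `factor`, `change_50s` (mean change while the cohort mean
#'   age is 50-59), `max_abs_change` (largest single-year absolute
#'   change), `max_abs_band` (largest decade-band-averaged absolute
#'   change, a noise-robust version of the former), `change_start` /
#'   `change_final` (signed mean change over the first and last five
#'   projection years); the baseline row (`factor = 0`) is 0 by
#'   construction of the paired seeds.
#' @export
sweep_initial <- function(cohort, fl_model, update_models,
                          config = simulation_config(),
                          thresholds = risk_thresholds(),
                          axes = c("bmi", "ratio"),
                          factors = c(-0.4, -0.2, 0.2, 0.4)) {
  allowed <- c("bmi", "ldl", "hdl", "ratio", "tg", "sbp", "hba1c",
               lifestyle_vars())
  bad <- setdiff(axes, allowed)
  if (length(bad)) stopf("unknown axis(es): %s", paste(bad, collapse = ", "))
  base_members <- baseline_state(cohort)
  cfg <- config
  if (is.null(cfg$horizon))
    cfg$horizon <- max(1L, as.integer(ceiling(79 - mean(base_members$age))))
  traj0 <- simulate_lifecourse(cohort, fl_model, update_models, cfg, thresholds)
  rows <- list(sens_row("baseline", 0, list(change_50s = 0, max_abs_change = 0,
                                            max_abs_band = 0, change_start = 0,
                                            change_final = 0)))
  for (ax in axes) for (f in factors) {
    varied <- vary_initial(cohort, ax, f,
                           seed = derive_seed(cfg$seed, match(ax, allowed) * 101 +
                                                round(1000 * f)),
                           thresholds = thresholds)
    traj <- simulate_lifecourse(varied, fl_model, update_models, cfg, thresholds)
    ch <- sens_changes(traj0, traj)
    rows[[length(rows) + 1L]] <- sens_row(ax, f, ch)
  }
  structure(do.call(rbind, rows),
            class = c("sensitivity_result", "data.frame"),
            kind = "initial", baseline = traj0)
}

#' One-way sensitivity to annual-update perturbations (S-2)
#'
#' For each variable and delta, multiplies every annual update prediction
#' of that variable by `1 + delta` (compounding over the projection) and
#' records the change in fatty-liver prevalence against the unperturbed
#' run with paired seeds.  The headline quantity is the change while the
#' cohort mean age is in the 50-59 band.
#'
#' @param cohort,fl_model,update_models,config,thresholds As in
#'   [sweep_initial()].
#' @param variables Updated variables to perturb (default `"bmi"`,
#'   `"ratio"`).
#' @param deltas Perturbations (default +/-0.5% and +/-1%); `|delta|`
#'   must be below 0.1.
#' @return A `sensitivity_result` data frame as in [sweep_initial()],
#'   with `axis` the perturbed variable and `factor` the delta.
#' @export
sweep_updates <- function(cohort, fl_model, update_models,
                          config = simulation_config(),
                          thresholds = risk_thresholds(),
                          variables = c("bmi", "ratio"),
                          deltas = c(-0.01, -0.005, 0.005, 0.01)) {
  if (any(abs(deltas) >= 0.1))
    stopf("deltas must satisfy |delta| < 0.1 (annual perturbation regime)")
  bad <- setdiff(variables, names(update_models))
  if (length(bad)) stopf("no update model for: %s", paste(bad, collapse = ", "))
  base_members <- baseline_state(cohort)
  cfg <- config
  if (is.null(cfg$horizon))
    cfg$horizon <- max(1L, as.integer(ceiling(79 - mean(base_members$age))))
  traj0 <- simulate_lifecourse(cohort, fl_model, update_models, cfg, thresholds)
  rows <- list(sens_row("baseline", 0, list(change_50s = 0, max_abs_change = 0,
                                            max_abs_band = 0, change_start = 0,
                                            change_final = 0)))
  trajs <- list()
  for (v in variables) for (d in deltas) {
    cfg_v <- cfg
    cfg_v$perturbation <- stats::setNames(1 + d, v)
    traj <- simulate_lifecourse(cohort, fl_model, update_models, cfg_v,
                                thresholds)
    ch <- sens_changes(traj0, traj)
    rows[[length(rows) + 1L]] <- sens_row(v, d, ch)
    trajs[[sprintf("%s%+g", v, d)]] <- traj
  }
  structure(do.call(rbind, rows),
            class = c("sensitivity_result", "data.frame"),
            kind = "updates", baseline = traj0, trajectories = trajs)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> (%s) %d arms\n", attr(x, "kind"),
              nrow(x) - 1L))
  NextMethod()
}
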