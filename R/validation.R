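#' Model calibration against the fitting cohort (V-1)
#'
#' Simulates a complete-case multi-wave cohort from its first wave across
#' the observed years and checks, for fatty liver and the two risk flags,
#' whether the observed per-year prevalence falls within +/- 2 SD of the
#' mean simulated prevalence (the Monte Carlo band).
#'
#' @param panel A complete-case `cohort_panel` with at least two observed
#'   waves.
#' @param fl_model An [fl_transition_model()].
#' @param update_models Named list of [covariate_update_model()]s.
#' @param config A [simulation_config()]; the horizon is fixed to the
#'   observed span.
#' @param thresholds A [risk_thresholds()].
#' @return A `v1_report`: data frame with one row per (year, quantity) —
#'   observed and simulated prevalence, SD and coverage — plus a
#'   `coverage` attribute (fraction of covered cells).
#' @export
calibrate_v1 <- function(panel, fl_model, update_models,
                         config = simulation_config(),
                         thresholds = risk_thresholds()) {
  years <- sort(unique(panel$year))
  if (length(years) < 2L) stopf("need at least 2 observed waves")
  if (anyNA(panel$fl)) stopf("panel must be complete-case (no missing status)")
  config$horizon <- length(years) - 1L
  traj <- simulate_lifecourse(panel, fl_model, update_models, config,
                              thresholds)
  p <- as.data.frame(panel)
  p$ratio <- ldl_hdl_ratio(p$ldl, p$hdl)
  obs <- do.call(rbind, lapply(seq_along(years), function(k) {
    w <- p[p$year == years[k], ]
    data.frame(step = k - 1L, year = years[k],
               quantity = c("fl", "bmi", "ratio"),
               observed = c(mean(w$fl), mean(w$bmi >= thresholds$bmi_hi),
                            mean(w$ratio >= thresholds$ratio_hi)))
  }))
  idx <- match(obs$step, traj$step)
  obs$simulated <- NA_real_
  obs$sd <- NA_real_
  for (q in c("fl", "bmi", "ratio")) {
    rows <- obs$quantity == q
    obs$simulated[rows] <- traj[[paste0(q, "_mean")]][idx[rows]]
    obs$sd[rows] <- traj[[paste0(q, "_sd")]][idx[rows]]
  }
  obs$covered <- abs(obs$observed - obs$simulated) <= 2 * obs$sd
  structure(obs, class = c("v1_report", "data.frame"),
            coverage = mean(obs$covered), trajectory = traj)
}

#' @export
print.v1_report <- function(x, ...) {
  cat(sprintf("<v1_report> calibration coverage: %.0f%% of year-quantity cells within +/- 2 SD\n",
              100 * attr(x, "coverage")))
  NextMethod()
}

#' Time-shift consistency across age cohorts (V-2)
#'
#' Projects each cohort until its members reach the 70-79 age band,
#' aligns the trajectories on cohort mean age (decade bands), and checks
#' pairwise overlap: within each shared band the band-mean prevalences of
#' two cohorts must differ by at most `2 * (SD_A + SD_B)`.  Overlap of
#' trajectories simulated from cohorts of different baseline ages is the
#' internal-consistency evidence that the natural history is a function
#' of age, not of the cohort chosen.
#'
#' @param cohorts List of at least two `cohort_panel`s with distinct
#'   baseline age bands.
#' @param fl_model,update_models,config,thresholds As in [calibrate_v1()].
#' @param quantity Prevalence compared (default `"fl"`).
#' @return A `v2_report`: data frame with one row per (band, cohort pair)
#'   and an `all_overlap` attribute.
#' @export
time_shift_v2 <- function(cohorts, fl_model, update_models,
                          config = simulation_config(),
                          thresholds = risk_thresholds(), quantity = "fl") {
  if (length(cohorts) < 2L) stopf("need at least 2 cohorts")
  trajs <- lapply(cohorts, function(co) {
    cfg <- config
    cfg$horizon <- NULL
    simulate_lifecourse(co, fl_model, update_models, cfg, thresholds)
  })
  band_stats <- lapply(trajs, function(tr) {
    band <- 10L * floor(tr$mean_age / 10)
    m <- tapply(tr[[paste0(quantity, "_mean")]], band, mean)
    s <- tapply(tr[[paste0(quantity, "_sd")]], band, mean)
    data.frame(band = as.integer(names(m)), mean = as.numeric(m),
               sd = as.numeric(s))
  })
  shared_any <- FALSE
  rows <- list()
  for (i in seq_along(band_stats)) for (j in seq_along(band_stats)) {
    if (j <= i) next
    shared <- intersect(band_stats[[i]]$band, band_stats[[j]]$band)
    if (!length(shared)) next
    shared_any <- TRUE
    a <- band_stats[[i]][match(shared, band_stats[[i]]$band), ]
    b <- band_stats[[j]][match(shared, band_stats[[j]]$band), ]
    rows[[length(rows) + 1L]] <- data.frame(
      band = shared, cohort_a = i, cohort_b = j,
      mean_a = a$mean, mean_b = b$mean,
      diff = abs(a$mean - b$mean), tol = 2 * (a$sd + b$sd),
      overlap = abs(a$mean - b$mean) <= 2 * (a$sd + b$sd))
  }
  if (!shared_any) stopf("cohorts share no age band (non-overlapping supports)")
  out <- do.call(rbind, rows)
  structure(out, class = c("v2_report", "data.frame"),
            all_overlap = all(out$overlap), trajectories = trajs)
}

#' @export
print.v2_report <- function(x, ...) {
  cat(sprintf("<v2_report> time-shift overlap in %d/%d shared band comparisons\n",
              sum(x$overlap), nrow(x)))
  NextMethod()
}

#' Comparison with externally observed prevalence (V-3)
#'
#' Compares the simulated fatty-liver prevalence per decade age band with
#' user-supplied external observations (surveys or check-up datasets the
#' model was not fitted to).  Values are supplied by the user, not
#' bundled.
#'
#' @param traj An `fl_trajectory`.
#' @param external Data frame with columns `band` (decade lower edge,
#'   e.g. 40), `prevalence`, and optionally `min`, `max` (the externally
#'   observed range).
#' @param quantity Trajectory quantity compared (default `"fl"`).
#' @return A `v3_report` data frame: per band the simulated mean, the
#'   difference, whether it lies inside the external `min`-`max` range,
#'   and a `comparable` flag (bands the trajectory never visits are
#'   marked not comparable and skipped, not failed).
#' @export
external_compare_v3 <- function(traj, external, quantity = "fl") {
  if (is.null(external) || !nrow(external)) stopf("external table is empty")
  if (!all(c("band", "prevalence") %in% names(external)))
    stopf("external must have columns 'band' and 'prevalence'")
  band <- 10L * floor(traj$mean_age / 10)
  sim <- tapply(traj[[paste0(quantity, "_mean")]], band, mean)
  out <- data.frame(band = as.integer(external$band),
                    external = external$prevalence)
  out$simulated <- as.numeric(sim[as.character(out$band)])
  out$comparable <- !is.na(out$simulated)
  out$difference <- out$simulated - out$external
  if (all(c("min", "max") %in% names(external))) {
    out$inside_range <- out$comparable & out$simulated >= external$min &
      out$simulated <= external$max
  }
  structure(out, class = c("v3_report", "data.frame"))
}
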