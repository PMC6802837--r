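#' Serialize fitted models to YAML
#'
#' Writes the transition model, the covariate update models and (when
#' present) the imputation model as a plain YAML document of coefficients,
#' residual SDs and fitted sample sizes.
#'
#' @param models Named list: `fl` (an [fl_transition_model()]), `updates`
#'   (named list of [covariate_update_model()]s), optionally `imputation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_models_yaml <- function(models, path) {
  to_list <- function(x) {
    if (inherits(x, "fl_transition_model"))
      return(list(beta0 = x$beta0, beta_fl = x$beta_fl, beta_bmi = x$beta_bmi,
                  beta_ratio = x$beta_ratio,
                  n = if (!is.null(x$selection)) x$selection$n else NA))
    if (inherits(x, "covariate_update_model"))
      return(list(variable = x$variable, coef = as.list(x$coef),
                  sigma = x$sigma, age_knot = x$age_knot, n = x$n))
    if (inherits(x, "fl_imputation_model"))
      return(list(coef = as.list(x$coef), covariates = x$covariates, n = x$n))
    x
  }
  out <- list()
  if (!is.null(models$fl)) out$transition <- to_list(models$fl)
  if (!is.null(models$updates)) out$updates <- lapply(models$updates, to_list)
  if (!is.null(models$imputation)) out$imputation <- to_list(models$imputation)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Export a transition table as CSV
#'
#' @param table An `fl_transition_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_study_config <- function() {
  list(
    synthetic = list(preset = "study_population", n_per_year = 2000,
                     years = 5, seed = 1),
    missingness = list(`20-29` = 0, `30-39` = 0.091, `40-69` = 0.955),
    fit = list(alpha = 0.05,
               candidates = c("fl", "bmi", "ratio", "tg", "sbp", "hba1c",
                              "smoker", "drinker", "exerciser", "shiftwork")),
    simulation = list(n_runs = 10, seed = 1),
    validation = list(external = NULL),
    sensitivity = list(
      initial_axes = c("bmi", "ratio", "tg", "sbp", "hba1c",
                       "smoker", "drinker", "exerciser", "shiftwork"),
      initial_factors = c(-0.4, -0.2, 0.2, 0.4),
      update_deltas = c(-0.01, -0.005, 0.005, 0.01))
  )
}

#' Read a study configuration from YAML
#'
#' Unspecified fields fall back to the package defaults; the sections
#' `synthetic` and `simulation` are mandatory.
#'
#' @param path YAML file, or `NULL` for the full default configuration.
#' @return A nested configuration list.
#' @export
read_study_config <- function(path = NULL) {
  cfg <- default_study_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!is.list(user[[sec]])) { cfg[[sec]] <- user[[sec]]; next }
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  for (sec in c("synthetic", "simulation")) {
    if (is.null(cfg[[sec]]))
      stopf("config section '%s' missing", sec)
  }
  cfg
}

#' Run the full study pipeline
#'
#' Executes generate -> missingness -> impute -> fit -> simulate ->
#' validate -> sensitivity and writes every artifact (models as YAML,
#' transition table / trajectories / reports / sensitivity grids as CSV,
#' life-course figures as PNG, and a deterministic manifest recording the
#' seeds and the configuration hash) to `output_dir`.  Running the same
#' configuration twice produces identical manifests and numeric outputs.
#'
#' @param config A configuration list from [read_study_config()] (or
#'   `NULL` for defaults).
#' @param output_dir Output directory, created if needed.
#' @param seed Overrides both the synthetic and simulation seeds when not
#'   `NULL` (the `--seed` of the command-line interface).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the panel, models, cohorts, trajectory,
#'   validation reports and sensitivity grids.
#' @export
run_study <- function(config = NULL, output_dir = "flcourse-out", seed = NULL,
                      quiet = FALSE) {
  if (is.null(config)) config <- read_study_config(NULL)
  for (sec in c("synthetic", "simulation"))
    if (is.null(config[[sec]])) stopf("config section '%s' missing", sec)
  if (!is.null(seed)) {
    config$synthetic$seed <- seed
    config$simulation$seed <- seed
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    say(name, "done in %.1f s", proc.time()[["elapsed"]] - t0)
    res
  }

  syn <- config$synthetic
  panel <- stage("generate", {
    maker <- switch(syn$preset %||% "study_population",
                    study_population = study_population_config,
                    cohort2 = cohort2_config,
                    stopf("unknown synthetic preset '%s'", syn$preset))
    gen_cfg <- maker(n_per_year = syn$n_per_year %||% 2000,
                     years = syn$years %||% 5, seed = syn$seed %||% 1)
    generate_population(gen_cfg)
  })

  panel_miss <- stage("missingness", {
    av <- unlist(config$missingness)
    apply_missingness(panel, av, seed = derive_seed(syn$seed %||% 1, 7))
  })

  imp <- stage("impute", {
    model <- fit_fl_imputation(panel_miss)
    list(model = model,
         panel = impute_missing_fl(panel_miss, model,
                                   seed = derive_seed(syn$seed %||% 1, 8)))
  })

  fits <- stage("fit", {
    # transition model from observed-status transitions only; imputed
    # statuses are used for cohort baselines, not for model derivation
    fl <- fit_fl_transition(panel_miss,
                            candidate_flags = config$fit$candidates %||%
                              c("fl", "bmi", "ratio"),
                            alpha = config$fit$alpha %||% 0.05)
    updates <- list(bmi = fit_covariate_update(panel_miss, "bmi",
                                               age_knot = 50, log = TRUE),
                    ratio = fit_covariate_update(panel_miss, "ratio",
                                                 age_knot = 50, log = TRUE))
    list(fl = fl, updates = updates)
  })

  cohorts <- stage("cohorts", {
    list(c1 = select_cohort(panel_miss, c(20, 99), complete_cases_only = TRUE),
         c2 = select_cohort(imp$panel, c(30, 39)),
         c3 = select_cohort(imp$panel, c(40, 49)),
         c4 = select_cohort(imp$panel, c(50, 59)))
  })

  sim_cfg <- simulation_config(n_runs = config$simulation$n_runs %||% 10,
                               seed = config$simulation$seed %||% 1)

  traj2 <- stage("simulate", {
    simulate_lifecourse(cohorts$c2, fits$fl, fits$updates, sim_cfg)
  })

  v1 <- stage("validate-v1", {
    calibrate_v1(cohorts$c1, fits$fl, fits$updates, sim_cfg)
  })
  v2 <- stage("validate-v2", {
    time_shift_v2(cohorts[c("c2", "c3", "c4")], fits$fl, fits$updates, sim_cfg)
  })
  v3 <- NULL
  if (!is.null(config$validation$external)) {
    v3 <- stage("validate-v3", {
      external_compare_v3(traj2, as.data.frame(config$validation$external))
    })
  }

  sens <- stage("sensitivity", {
    list(initial = sweep_initial(cohorts$c2, fits$fl, fits$updates, sim_cfg,
                                 axes = config$sensitivity$initial_axes %||%
                                   c("bmi", "ratio"),
                                 factors = config$sensitivity$initial_factors %||%
                                   c(-0.4, -0.2, 0.2, 0.4)),
         updates = sweep_updates(cohorts$c2, fits$fl, fits$updates, sim_cfg,
                                 deltas = config$sensitivity$update_deltas %||%
                                   c(-0.01, -0.005, 0.005, 0.01)))
  })

  stage("write", {
    out <- function(f) file.path(output_dir, f)
    write_panel(imp$panel, out("panel.csv"))
    write_models_yaml(list(fl = fits$fl, updates = fits$updates,
                           imputation = imp$model), out("models.yaml"))
    write_transition_table(build_table(fits$fl), out("transition_table.csv"))
    utils::write.csv(as.data.frame(traj2), out("trajectory_cohort2.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(v1), out("validation_v1.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(v2), out("validation_v2.csv"),
                     row.names = FALSE)
    if (!is.null(v3))
      utils::write.csv(as.data.frame(v3), out("validation_v3.csv"),
                       row.names = FALSE)
    utils::write.csv(as.data.frame(sens$initial), out("sensitivity_initial.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sens$updates), out("sensitivity_updates.csv"),
                     row.names = FALSE)
    for (q in c("fl", "bmi", "ratio")) {
      ggplot2::ggsave(out(sprintf("trajectory_%s.png", q)),
                      plot(traj2, quantity = q),
                      width = 6, height = 4, dpi = 120)
    }
    cfg_path <- out("config.yaml")
    yaml::write_yaml(config, cfg_path)
    manifest <- list(
      package = "flcourse",
      config_md5 = unname(tools::md5sum(cfg_path)),
      seeds = list(synthetic = syn$seed %||% 1,
                   simulation = sim_cfg$seed),
      n_person_years = nrow(panel),
      n_transitions = fits$fl$selection$n,
      transition_coefficients = list(beta0 = fits$fl$beta0,
                                     beta_fl = fits$fl$beta_fl,
                                     beta_bmi = fits$fl$beta_bmi,
                                     beta_ratio = fits$fl$beta_ratio),
      v1_coverage = attr(v1, "coverage"),
      v2_all_overlap = attr(v2, "all_overlap"))
    yaml::write_yaml(manifest, out("manifest.yaml"))
    TRUE
  })

  invisible(list(panel = imp$panel, models = fits, imputation = imp$model,
                 cohorts = cohorts, trajectory = traj2, v1 = v1, v2 = v2,
                 v3 = v3, sensitivity = sens, output_dir = output_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
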