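#' Annual transition model for fatty-liver presence
#'
#' The state transition of fatty liver is governed by a main-effects
#' logistic model on the logit scale:
#'
#' \deqn{\mathrm{logit}\, P(FL_{t+1}=1) = \beta_0 + \beta_{FL} FL_t +
#'       \beta_{BMI} [BMI_t \ge 25] + \beta_{ratio} [LDL/HDL_t \ge 2]}
#'
#' where the predictors are the state and flags *before* transition.  The
#' four coefficients induce an 8-cell transition table (one probability per
#' combination of prior status, BMI flag and ratio flag).  Interaction
#' terms are deliberately absent: the published table is additive on the
#' log-odds scale to within printing precision, which [fit_table_main_effects()]
#' verifies.
#'
#' @param beta0 Intercept (log-odds of incident fatty liver with all
#'   predictors at their normal level).
#' @param beta_fl Log-odds increment for fatty liver present at `t`.
#' @param beta_bmi Log-odds increment for BMI >= 25 kg/m2.
#' @param beta_ratio Log-odds increment for LDL-C/HDL-C >= 2.
#' @return An object of class `fl_transition_model`.
#' @details Risk-factor coefficients must be non-negative (risk-increasing);
#'   a zero coefficient represents a term eliminated during model selection.
#' @export
fl_transition_model <- function(beta0, beta_fl, beta_bmi, beta_ratio) {
  b <- c(beta0 = beta0, beta_fl = beta_fl, beta_bmi = beta_bmi,
         beta_ratio = beta_ratio)
  if (any(!is.finite(b))) stopf("all coefficients must be finite")
  if (any(b[-1L] < 0))
    stopf("beta_fl, beta_bmi and beta_ratio must be non-negative (risk-increasing)")
  structure(as.list(b), class = "fl_transition_model")
}

#' @export
print.fl_transition_model <- function(x, ...) {
  cat("<fl_transition_model> logit P(FL') =",
      sprintf("%.3f + %.3f*FL + %.3f*[BMI>=25] + %.3f*[LDL/HDL>=2]\n",
              x$beta0, x$beta_fl, x$beta_bmi, x$beta_ratio))
  if (!is.null(x$selection)) {
    cat(sprintf("  fitted on %d person-transitions; eliminated: %s\n",
                x$selection$n,
                if (length(x$selection$eliminated))
                  paste(x$selection$eliminated, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Transition probability for one cell of the state space
#'
#' Inverse-logit of the model's linear predictor, vectorized over the
#' three binary inputs.
#'
#' @param model A [fl_transition_model()].
#' @param fl Prior fatty-liver status, 0/1.
#' @param bmi_flag BMI >= 25 indicator, 0/1.
#' @param ratio_flag LDL-C/HDL-C >= 2 indicator, 0/1.
#' @return Probability that fatty liver is present next year.
#' @export
transition_probability <- function(model, fl, bmi_flag, ratio_flag) {
  stopifnot(inherits(model, "fl_transition_model"))
  if (any(!(fl %in% 0:1)) || any(!(bmi_flag %in% 0:1)) ||
      any(!(ratio_flag %in% 0:1)))
    stopf("fl, bmi_flag and ratio_flag must be 0 or 1")
  stats::plogis(model$beta0 + model$beta_fl * fl +
                model$beta_bmi * bmi_flag + model$beta_ratio * ratio_flag)
}

#' Expand a transition model into its 8-cell table
#'
#' @param model A [fl_transition_model()].
#' @return Data frame of class `fl_transition_table` with columns `fl`,
#'   `bmi`, `ratio` (the 0/1 cell indices) and `prob`; monotone
#'   nondecreasing in each index.
#' @export
build_table <- function(model) {
  cells <- expand.grid(ratio = 0:1, bmi = 0:1, fl = 0:1)[, c("fl", "bmi", "ratio")]
  cells <- cells[order(cells$fl, cells$bmi, cells$ratio), ]
  rownames(cells) <- NULL
  cells$prob <- transition_probability(model, cells$fl, cells$bmi, cells$ratio)
  structure(cells, class = c("fl_transition_table", "data.frame"))
}

#' Reference transition table for adult Japanese men
#'
#' The eight published annual transition probabilities for the presence of
#' fatty liver, estimated by multivariate logistic regression from a 5-year
#' occupational health-examination cohort of Japanese men aged 20-69.
#' Rows are indexed by prior fatty-liver status and the two risk flags
#' before transition.  Used throughout as the calibration surface for the
#' synthetic generator and as the fixture for table-reconstruction checks.
#'
#' @return An `fl_transition_table` data frame (8 rows).
#' @export
reference_transition_table <- function() {
  cells <- expand.grid(ratio = 0:1, bmi = 0:1, fl = 0:1)[, c("fl", "bmi", "ratio")]
  cells <- cells[order(cells$fl, cells$bmi, cells$ratio), ]
  rownames(cells) <- NULL
  cells$prob <- c(0.031, 0.074, 0.072, 0.164, 0.649, 0.823, 0.819, 0.919)
  structure(cells, class = c("fl_transition_table", "data.frame"))
}

#' Fit a main-effects model to transition-table cells
#'
#' Unweighted least squares of the cell log-odds on an intercept and the
#' three binary indices.  With all eight cells this is the minimum-norm
#' main-effects reconstruction of the table; with seven cells it predicts
#' the held-out cell.  Cell-level sample sizes are not needed (and for the
#' published table are unavailable), hence the unweighted fit.
#'
#' @param cells Data frame with columns `fl`, `bmi`, `ratio` (0/1) and
#'   `prob` in (0,1); at least 4 cells spanning all three indices.
#' @return An [fl_transition_model()].
#' @export
fit_table_main_effects <- function(cells) {
  cells <- as.data.frame(cells)
  need <- c("fl", "bmi", "ratio", "prob")
  if (!all(need %in% names(cells)))
    stopf("cells must have columns fl, bmi, ratio, prob")
  if (nrow(cells) < 4L) stopf("need at least 4 cells")
  if (any(cells$prob <= 0 | cells$prob >= 1))
    stopf("cell probabilities must lie strictly in (0, 1)")
  X <- cbind(1, cells$fl, cells$bmi, cells$ratio)
  if (qr(X)$rank < 4L)
    stopf("cells do not span all three indices (rank-deficient design)")
  fit <- stats::lm.fit(X, stats::qlogis(cells$prob))
  b <- fit$coefficients
  fl_transition_model(b[1L], b[2L], b[3L], b[4L])
}

#' Stationary prevalence of the two-state fatty-liver chain
#'
#' For fixed risk flags the model is a two-state Markov chain with
#' incidence probability `p01 = P(FL'=1 | FL=0)` and persistence
#' probability `p11 = P(FL'=1 | FL=1)`.  Its long-run prevalence is the
#' fixed point `p01 / (p01 + 1 - p11)`.  Serves as the closed-form oracle
#' for the simulator's long-run behaviour under frozen covariates.
#'
#' @param p01 Annual incidence probability.
#' @param p11 Annual persistence probability.
#' @return Stationary prevalence in \[0, 1\]; vectorized.
#' @export
stationary_prevalence <- function(p01, p11) {
  check_fraction(p01, "p01"); check_fraction(p11, "p11")
  denom <- p01 + 1 - p11
  if (any(denom <= 0))
    stopf("degenerate chain (p01 = 0 and p11 = 1): no unique stationary point")
  p01 / denom
}

#' Fit the fatty-liver transition model from a longitudinal panel
#'
#' Builds all person-transitions (consecutive-year pairs with observed
#' fatty-liver status at both ends), dichotomizes the candidate risk
#' factors at `t`, and fits a logistic regression of status at `t+1` by
#' forced entry followed by backward elimination: at each step the term
#' with the largest likelihood-ratio p-value `>= alpha` is removed (ties
#' broken by term order) until all surviving terms have `p < alpha`.
#'
#' @param panel A `cohort_panel` with at least two consecutive waves of
#'   observed status.
#' @param candidate_flags Character vector of candidate predictors at `t`:
#'   `"fl"` (prior status) plus any of `"bmi"`, `"ldl"`, `"hdl"`,
#'   `"ratio"`, `"tg"`, `"sbp"`, `"hba1c"`, `"smoker"`, `"drinker"`,
#'   `"exerciser"`, `"shiftwork"`.
#' @param alpha Significance level for elimination (default 0.05).
#' @param thresholds A [risk_thresholds()] used for dichotomization.
#' @return An [fl_transition_model()] whose eliminated risk-flag terms are
#'   zero; `$selection` records the fitted n, eliminated terms, and the
#'   coefficients of any surviving non-canonical terms.
#' @export
fit_fl_transition <- function(panel, candidate_flags = c("fl", "bmi", "ratio"),
                              alpha = 0.05, thresholds = risk_thresholds()) {
  allowed <- c("fl", "bmi", "ldl", "hdl", "ratio", "tg", "sbp", "hba1c",
               lifestyle_vars())
  bad <- setdiff(candidate_flags, allowed)
  if (length(bad)) stopf("unknown candidate flag(s): %s", paste(bad, collapse = ", "))
  tr <- build_transitions(panel, thresholds)
  if (nrow(tr) < 50L)
    stopf("only %d person-transitions with observed status; need at least 50",
          nrow(tr))
  dat <- tr[c("fl_next", candidate_flags)]
  terms <- candidate_flags
  eliminated <- character(0)
  repeat {
    fml <- stats::reformulate(if (length(terms)) terms else "1", response = "fl_next")
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))
    if (!length(terms)) break
    if (max(abs(stats::coef(fit)), na.rm = TRUE) > 15)
      stopf("possible complete separation: a coefficient exceeds 15 on the logit scale")
    dr <- suppressWarnings(stats::drop1(fit, test = "Chisq"))
    pv <- dr[["Pr(>Chi)"]][-1L]      # first row is <none>
    names(pv) <- rownames(dr)[-1L]
    if (all(pv < alpha, na.rm = TRUE)) break
    worst <- names(pv)[which.max(replace(pv, is.na(pv), 1))]
    eliminated <- c(eliminated, worst)
    terms <- setdiff(terms, worst)
  }
  cf <- stats::coef(fit)
  get <- function(nm) {
    hit <- cf[names(cf) %in% c(nm, paste0(nm, "TRUE"))]
    if (length(hit)) unname(hit) else 0
  }
  extra_terms <- setdiff(terms, c("fl", "bmi", "ratio"))
  if (length(extra_terms))
    warning(sprintf("non-canonical term(s) survived elimination: %s",
                    paste(extra_terms, collapse = ", ")))
  model <- fl_transition_model(unname(cf[["(Intercept)"]]),
                               get("fl"), get("bmi"), get("ratio"))
  model$selection <- list(n = nrow(tr), alpha = alpha, eliminated = eliminated,
                          extra = cf[names(cf) %in% c(extra_terms,
                                                      paste0(extra_terms, "TRUE"))])
  model
}

# One row per person-transition: flags and status at t, status at t+1.
build_transitions <- function(panel, thresholds = risk_thresholds()) {
  p <- as.data.frame(panel)
  o <- order(p$person_id, p$year)
  p <- p[o, ]
  n <- nrow(p)
  if (n < 2L) return(data.frame())
  cur <- p[-n, ]
  nxt <- p[-1L, ]
  ok <- cur$person_id == nxt$person_id & nxt$year == cur$year + 1L &
        !is.na(cur$fl) & !is.na(nxt$fl)
  cur <- cur[ok, ]
  nxt <- nxt[ok, ]
  fx <- risk_flags(cur, thresholds)
  out <- data.frame(person_id = cur$person_id, year = cur$year, age = cur$age,
                    fl = cur$fl, fl_next = nxt$fl)
  for (v in names(fx)) out[[v]] <- fx[[v]]
  for (v in lifestyle_vars()) out[[v]] <- cur[[v]]
  out
}
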