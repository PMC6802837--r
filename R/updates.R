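#' Stochastic annual update model for a continuous risk factor
#'
#' Risk-factor trajectories are evolved by a first-order autoregressive
#' prediction rule with a piecewise-linear age profile and Gaussian
#' residuals:
#'
#' \deqn{V_{t+1} = a + b\,V_t + c\,\mathrm{age} + d\,(\mathrm{age}-k)_+ +
#'       \epsilon,\qquad \epsilon \sim N(0, \sigma^2)}
#'
#' The hinge term at age `k` lets the expected life-course rise to middle
#' age and decline afterwards (the shape BMI follows in national survey
#' data).  Models are fitted from panel data by ordinary least squares;
#' the residual SD is taken from the fit residuals.
#'
#' For strictly positive, right-skewed variables (BMI, the cholesterol
#' ratio) the autoregression can instead be specified on the log scale
#' (`log = TRUE`): the regression relates `log V_{t+1}` to `log V_t`, the
#' residual is Gaussian on the log scale, and predictions are reported on
#' the natural scale.  A Gaussian natural-scale update drives the
#' long-run marginal towards symmetry and thereby biases the fraction
#' beyond an above-mean cut-point; the log-scale form preserves the
#' right skew these variables show in examination data.
#'
#' @param variable Variable name (`"bmi"`, `"ratio"`, ...).
#' @param coef Named numeric vector `intercept`, `slope`, and optionally
#'   `age`, `age_hinge`.
#' @param sigma Residual standard deviation (same units as the variable,
#'   or log units when `log = TRUE`).
#' @param age_knot Hinge location in years (default 55).
#' @param log Autoregression on the log scale (default `FALSE`).
#' @param n Number of (t, t+1) pairs the model was fitted on (0 if
#'   constructed directly).
#' @return An object of class `covariate_update_model`.
#' @export
covariate_update_model <- function(variable, coef, sigma, age_knot = 55,
                                   log = FALSE, n = 0L) {
  if (!all(c("intercept", "slope") %in% names(coef)))
    stopf("coef must contain at least 'intercept' and 'slope'")
  if (is.na(sigma) || sigma < 0) stopf("residual SD must be non-negative")
  structure(list(variable = variable,
                 coef = c(intercept = unname(coef["intercept"]),
                          slope = unname(coef["slope"]),
                          age = if ("age" %in% names(coef)) unname(coef["age"]) else 0,
                          age_hinge = if ("age_hinge" %in% names(coef))
                            unname(coef["age_hinge"]) else 0),
                 sigma = sigma, age_knot = age_knot, log = isTRUE(log),
                 n = as.integer(n)),
            class = "covariate_update_model")
}

#' @export
print.covariate_update_model <- function(x, ...) {
  v <- if (x$log) sprintf("log(%s)", x$variable) else x$variable
  cat(sprintf("<covariate_update_model> %s' = %.3f + %.3f*%s + %.4f*age + %.4f*(age-%g)+ ; sigma = %.3f (n = %d)\n",
              v, x$coef["intercept"], x$coef["slope"], v,
              x$coef["age"], x$coef["age_hinge"], x$age_knot, x$sigma, x$n))
  invisible(x)
}

#' Deterministic part of the annual update
#'
#' @param model A [covariate_update_model()].
#' @param value Current value(s).
#' @param age Current age(s) in years.
#' @return Predicted next-year value(s) on the natural scale, before the
#'   residual draw.
#' @export
predict_update <- function(model, value, age) {
  stopifnot(inherits(model, "covariate_update_model"))
  b <- model$coef
  v <- if (model$log) log(value) else value
  pred <- unname(b["intercept"] + b["slope"] * v + b["age"] * age +
                 b["age_hinge"] * pmax(age - model$age_knot, 0))
  if (model$log) exp(pred) else pred
}

#' Fit an annual update model from a panel
#'
#' Ordinary least squares of the variable at `t+1` on its value at `t`
#' plus the age-profile terms, over all consecutive-year pairs in the
#' panel.  `variable = "ratio"` fits the LDL-C/HDL-C ratio (computed from
#' the panel's LDL-C and HDL-C columns); the ratio is updated as a single
#' variable because the ratio, not its components, predicts fatty liver.
#'
#' @param panel A `cohort_panel` with at least two consecutive waves.
#' @param variable One of the continuous panel variables or `"ratio"`.
#' @param age_terms Include the age profile (default `TRUE`).
#' @param age_knot Hinge location for the age profile (default 55).
#' @param log Fit the autoregression on the log scale (default `FALSE`).
#' @return A [covariate_update_model()].
#' @export
fit_covariate_update <- function(panel, variable, age_terms = TRUE,
                                 age_knot = 55, log = FALSE) {
  ok_vars <- c(continuous_vars(), "ratio")
  if (!variable %in% ok_vars)
    stopf("variable must be one of: %s", paste(ok_vars, collapse = ", "))
  p <- as.data.frame(panel)
  p$ratio <- ldl_hdl_ratio(p$ldl, p$hdl)
  o <- order(p$person_id, p$year)
  p <- p[o, ]
  n <- nrow(p)
  cur <- p[-n, ]
  nxt <- p[-1L, ]
  ok <- cur$person_id == nxt$person_id & nxt$year == cur$year + 1L &
        !is.na(cur[[variable]]) & !is.na(nxt[[variable]])
  v0 <- cur[[variable]][ok]
  v1 <- nxt[[variable]][ok]
  age <- cur$age[ok]
  if (length(v0) < 50L)
    stopf("only %d (t, t+1) pairs for '%s'; need at least 50", length(v0), variable)
  if (log) { v0 <- base::log(v0); v1 <- base::log(v1) }
  if (age_terms) {
    X <- cbind(1, v0, age, pmax(age - age_knot, 0))
    cn <- c("intercept", "slope", "age", "age_hinge")
  } else {
    X <- cbind(1, v0)
    cn <- c("intercept", "slope")
  }
  fit <- stats::lm.fit(X, v1)
  cf <- stats::setNames(fit$coefficients, cn)
  cf[is.na(cf)] <- 0
  sigma <- sqrt(sum(fit$residuals^2) / max(1L, length(v1) - ncol(X)))
  covariate_update_model(variable, cf, sigma, age_knot = age_knot,
                         log = log, n = length(v1))
}
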