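#' Imputation model for missing fatty-liver status
#'
#' Ultrasonography is offered age-dependently in the emulated examination
#' programme, so fatty-liver status is unobserved for most participants
#' under 40.  Missing statuses are estimated by a same-year multivariate
#' logistic regression of observed status on the dichotomized risk flags
#' and age, fitted to participants aged 30-69 (the age range where both
#' observed statuses and the covariates of the missing group are
#' represented).
#'
#' @param panel A `cohort_panel`.
#' @param covariates Flag names entering the model (default `c("bmi",
#'   "ratio")`, the predictors that carry the fatty-liver signal).
#' @param age_range Ages of the fitting records (default `c(30, 69)`).
#' @param include_age Add a linear age term (default `TRUE`).
#' @param thresholds A [risk_thresholds()].
#' @return An object of class `fl_imputation_model` holding the fitted
#'   logistic coefficients; predicted probabilities are strictly inside
#'   (0, 1).
#' @export
fit_fl_imputation <- function(panel, covariates = c("bmi", "ratio"),
                              age_range = c(30, 69), include_age = TRUE,
                              thresholds = risk_thresholds()) {
  p <- as.data.frame(panel)
  p <- p[!is.na(p$fl) & p$age >= age_range[1L] & p$age <= age_range[2L], ]
  if (nrow(p) < 50L)
    stopf("only %d observed-status records in the fitting age range", nrow(p))
  fx <- risk_flags(p, thresholds)
  bad <- setdiff(covariates, names(fx))
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  dat <- cbind(data.frame(fl = p$fl, age = p$age), fx[covariates])
  terms <- c(covariates, if (include_age) "age")
  fit <- stats::glm(stats::reformulate(terms, response = "fl"),
                    family = stats::binomial(), data = dat)
  structure(list(coef = stats::coef(fit), covariates = covariates,
                 include_age = include_age, thresholds = thresholds,
                 n = nrow(dat)),
            class = "fl_imputation_model")
}

#' @export
print.fl_imputation_model <- function(x, ...) {
  cat("<fl_imputation_model> logit P(FL) =",
      paste(sprintf("%.3f*%s", x$coef, names(x$coef)), collapse = " + "), "\n")
  invisible(x)
}

# Predicted same-year probability of fatty-liver presence.
predict_imputation <- function(model, data) {
  fx <- risk_flags(data, model$thresholds)
  eta <- rep(model$coef[["(Intercept)"]], nrow(data))
  for (v in model$covariates) {
    nm <- if (paste0(v, "TRUE") %in% names(model$coef)) paste0(v, "TRUE") else v
    eta <- eta + model$coef[[nm]] * as.numeric(fx[[v]])
  }
  if (model$include_age) eta <- eta + model$coef[["age"]] * data$age
  stats::plogis(eta)
}

#' Impute missing fatty-liver statuses
#'
#' Replaces each missing status by a Bernoulli draw at the imputation
#' model's predicted probability.  Observed statuses are never altered,
#' and the result is deterministic given the seed.
#'
#' @param panel A `cohort_panel`.
#' @param model A [fit_fl_imputation()] model.
#' @param seed Integer seed for the Bernoulli draws.
#' @return The panel with every `fl` observed; metadata gains an
#'   `imputed_n` entry.
#' @export
impute_missing_fl <- function(panel, model, seed = 1L) {
  stopifnot(inherits(model, "fl_imputation_model"))
  miss <- which(is.na(panel$fl))
  if (!length(miss)) return(panel)
  rows <- as.data.frame(panel)[miss, ]
  if (any(vapply(continuous_vars(), function(v) anyNA(rows[[v]]), logical(1))))
    stopf("imputation covariates missing for some records with missing status")
  p <- predict_imputation(model, rows)
  draw <- with_seed(seed, stats::rbinom(length(miss), 1L, p))
  panel$fl[miss] <- as.integer(draw)
  meta <- attr(panel, "meta")
  meta$imputed_n <- length(miss)
  attr(panel, "meta") <- meta
  panel
}
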