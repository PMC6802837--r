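#' Risk-category thresholds
#'
#' Cut-points used to dichotomize the continuous risk factors into the
#' normal/abnormal categories entering the transition model and the
#' sensitivity analysis.  Defaults follow the risk-stratification criteria
#' commonly used in Japanese health examinations: BMI >= 25 kg/m2,
#' LDL-C >= 120 mg/dl, HDL-C < 40 mg/dl, LDL-C/HDL-C ratio >= 2,
#' TG >= 150 mg/dl, SBP >= 130 mmHg, HbA1c >= 6.5%.
#'
#' All rules are inclusive-`>=` except HDL-C, whose abnormal direction is
#' strictly-`<` (low HDL-C is the risk state).  A value exactly at a `>=`
#' cut-point is abnormal; HDL-C exactly at 40 is normal.
#'
#' @param bmi_hi,ldl_hi,hdl_lo,ratio_hi,tg_hi,sbp_hi,hba1c_hi Numeric
#'   cut-points (units: kg/m2, mg/dl, mg/dl, unitless, mg/dl, mmHg, %).
#' @return An object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(bmi_hi = 25, ldl_hi = 120, hdl_lo = 40,
                            ratio_hi = 2, tg_hi = 150, sbp_hi = 130,
                            hba1c_hi = 6.5) {
  th <- list(bmi_hi = bmi_hi, ldl_hi = ldl_hi, hdl_lo = hdl_lo,
             ratio_hi = ratio_hi, tg_hi = tg_hi, sbp_hi = sbp_hi,
             hba1c_hi = hba1c_hi)
  for (nm in names(th)) {
    if (!is.numeric(th[[nm]]) || length(th[[nm]]) != 1L || is.na(th[[nm]]) ||
        th[[nm]] <= 0)
      stopf("threshold '%s' must be a single positive number", nm)
  }
  structure(th, class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat("<risk_thresholds>\n")
  cat(sprintf("  BMI >= %g kg/m2, LDL-C >= %g mg/dl, HDL-C < %g mg/dl\n",
              x$bmi_hi, x$ldl_hi, x$hdl_lo))
  cat(sprintf("  LDL-C/HDL-C >= %g, TG >= %g mg/dl, SBP >= %g mmHg, HbA1c >= %g%%\n",
              x$ratio_hi, x$tg_hi, x$sbp_hi, x$hba1c_hi))
  invisible(x)
}

#' LDL-C / HDL-C cholesterol ratio
#'
#' @param ldl LDL-C in mg/dl.
#' @param hdl HDL-C in mg/dl; must be strictly positive.
#' @return `ldl / hdl` (unitless), vectorized.
#' @export
ldl_hdl_ratio <- function(ldl, hdl) {
  if (any(!is.na(hdl) & hdl <= 0)) stopf("hdl must be strictly positive")
  ldl / hdl
}

#' Dichotomize risk factors into normal/abnormal flags (vectorized)
#'
#' Applies the threshold rules to whole panels or member tables.  The
#' abnormal direction is `>=` for BMI, LDL-C, the LDL-C/HDL-C ratio, TG,
#' SBP and HbA1c, and `<` for HDL-C.
#'
#' @param data Data frame with columns `bmi`, `ldl`, `hdl`, `tg`, `sbp`,
#'   `hba1c` (a `ratio` column is used if present, otherwise computed).
#' @param thresholds A [risk_thresholds()] object.
#' @return Data frame of logicals: `bmi`, `ldl`, `hdl`, `ratio`, `tg`,
#'   `sbp`, `hba1c` (TRUE = abnormal).
#' @export
risk_flags <- function(data, thresholds = risk_thresholds()) {
  ratio <- if ("ratio" %in% names(data)) data$ratio
           else ldl_hdl_ratio(data$ldl, data$hdl)
  data.frame(
    bmi   = data$bmi >= thresholds$bmi_hi,
    ldl   = data$ldl >= thresholds$ldl_hi,
    hdl   = data$hdl < thresholds$hdl_lo,
    ratio = ratio >= thresholds$ratio_hi,
    tg    = data$tg >= thresholds$tg_hi,
    sbp   = data$sbp >= thresholds$sbp_hi,
    hba1c = data$hba1c >= thresholds$hba1c_hi
  )
}

#' Risk-category profile of a single person-year record
#'
#' @param record One-row data frame or named list with the continuous
#'   fields `bmi`, `ldl`, `hdl`, `tg`, `sbp`, `hba1c` (lifestyle booleans
#'   are passed through when present).
#' @param thresholds A [risk_thresholds()] object.
#' @return A named list of abnormality flags (class `risk_profile`);
#'   dichotomizing is idempotent and a pure function of the record and the
#'   thresholds.
#' @export
dichotomize <- function(record, thresholds = risk_thresholds()) {
  record <- as.list(record)
  for (v in continuous_vars()) {
    if (is.null(record[[v]]) || is.na(record[[v]]))
      stopf("cannot dichotomize: field '%s' is missing", v)
  }
  flags <- as.list(risk_flags(as.data.frame(record[continuous_vars()]), thresholds))
  for (v in lifestyle_vars())
    if (!is.null(record[[v]])) flags[[v]] <- isTRUE(record[[v]])
  structure(flags, class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile> abnormal:",
      paste(names(x)[vapply(x, isTRUE, logical(1))], collapse = ", "), "\n")
  invisible(x)
}
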