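#' Longitudinal person-year panels
#'
#' A cohort panel holds one row per person and examination year: age,
#' fatty-liver status by ultrasonography (`fl`, coded 0 = absent,
#' 1 = present, `NA` = not examined), six continuous risk factors and four
#' lifestyle booleans.  Panels are plain data frames of class
#' `"cohort_panel"` so every base-R and tidyverse verb applies; the class
#' carries validation and a metadata attribute (observation years, source
#' tag).
#'
#' @name cohort_panel
NULL

panel_columns <- function() {
  c("person_id", "year", "age", "fl", "bmi", "ldl", "hdl", "tg",
    "sbp", "hba1c", "smoker", "drinker", "exerciser", "shiftwork")
}

continuous_vars <- function() c("bmi", "ldl", "hdl", "tg", "sbp", "hba1c")

lifestyle_vars <- function() c("smoker", "drinker", "exerciser", "shiftwork")

#' Construct a cohort panel from a data frame
#'
#' @param data Data frame with columns `person_id`, `year`, `age`, `fl`,
#'   `bmi`, `ldl`, `hdl`, `tg`, `sbp`, `hba1c`, `smoker`, `drinker`,
#'   `exerciser`, `shiftwork`.
#' @param source Character tag recorded in the panel metadata.
#' @param validate Check the panel invariants (default `TRUE`).
#' @return A `cohort_panel` (data frame).
#' @export
as_cohort_panel <- function(data, source = "user", validate = TRUE) {
  missing_cols <- setdiff(panel_columns(), names(data))
  if (length(missing_cols))
    stopf("panel is missing column(s): %s", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(data), panel_columns())
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  data <- as.data.frame(data)[panel_columns()]
  data$person_id <- as.character(data$person_id)
  data$year <- as.integer(data$year)
  data$age <- as.integer(data$age)
  data$fl <- as.integer(data$fl)
  for (v in lifestyle_vars()) data[[v]] <- as.logical(data[[v]])
  rownames(data) <- NULL
  attr(data, "meta") <- list(years = sort(unique(data$year)), source = source)
  class(data) <- c("cohort_panel", "data.frame")
  if (validate) validate_panel(data)
  data
}

#' Validate cohort panel invariants
#'
#' Checks: at most one record per (person, year); within a person, age
#' advances by exactly one per calendar year; ages in \[20, 99\]; continuous
#' risk factors strictly positive when present; `fl` in \{0, 1, NA\}.
#'
#' @param panel A `cohort_panel`.
#' @return The panel, invisibly; errors describe the first violation.
#' @export
validate_panel <- function(panel) {
  if (anyDuplicated(panel[c("person_id", "year")]))
    stopf("panel has more than one record per (person_id, year)")
  if (any(is.na(panel$age)) || any(panel$age < 20) || any(panel$age > 99))
    stopf("ages must lie in [20, 99]")
  bad_fl <- !is.na(panel$fl) & !(panel$fl %in% c(0L, 1L))
  if (any(bad_fl))
    stopf("fl must be coded 0/1/NA (first bad row: %d)", which(bad_fl)[1L])
  for (v in continuous_vars()) {
    x <- panel[[v]]
    if (any(!is.na(x) & x <= 0)) stopf("'%s' must be strictly positive", v)
  }
  # age must advance in lockstep with calendar year within each person
  o <- order(panel$person_id, panel$year)
  pid <- panel$person_id[o]
  same <- pid[-1L] == pid[-length(pid)]
  if (any(same)) {
    dy <- diff(panel$year[o])[same]
    da <- diff(panel$age[o])[same]
    if (any(da != dy))
      stopf("age must increase by exactly 1 per calendar year within a person")
  }
  invisible(panel)
}

#' @export
print.cohort_panel <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<cohort_panel> %d person-years, %d persons, years %s (%s)\n",
              nrow(x), length(unique(x$person_id)),
              paste(range(x$year), collapse = "-"),
              if (is.null(meta$source)) "user" else meta$source))
  NextMethod()
}

#' Read / write a person-year panel as CSV
#'
#' The on-disk schema is one row per person-year with columns exactly
#' `person_id, year, age, fl, bmi, ldl, hdl, tg, sbp, hba1c, smoker,
#' drinker, exerciser, shiftwork`; `fl` is coded 0/1/NA and the lifestyle
#' columns 0/1.  Writing then reading reproduces the panel exactly.
#'
#' @param path File path.
#' @param panel A `cohort_panel`.
#' @return `read_panel` returns a `cohort_panel`; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(panel_columns(), names(raw))
  if (length(missing_cols))
    stopf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  bad <- which(!is.na(raw$fl) & !(raw$fl %in% c(0, 1)))
  if (length(bad))
    stopf("%s: fl must be 0/1/NA (row %d has '%s')", path, bad[1L], raw$fl[bad[1L]])
  for (v in lifestyle_vars()) raw[[v]] <- raw[[v]] != 0
  as_cohort_panel(raw, source = basename(path))
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)[panel_columns()]
  for (v in lifestyle_vars()) out[[v]] <- as.integer(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Baseline (first observed wave) state of each cohort member
#'
#' Extracts each person's first observed record and adds the LDL-C/HDL-C
#' ratio column the simulator evolves.  Members whose baseline fatty-liver
#' status is missing are rejected: impute first (see [impute_missing_fl()]).
#'
#' @param panel A `cohort_panel`.
#' @param require_fl Require observed (or imputed) baseline status.
#' @return Data frame with one row per person: `person_id`, `age`, `fl`,
#'   `bmi`, `ratio`, plus the remaining panel fields.
#' @export
baseline_state <- function(panel, require_fl = TRUE) {
  o <- order(panel$person_id, panel$year)
  p <- as.data.frame(panel)[o, ]
  first <- !duplicated(p$person_id)
  base <- p[first, ]
  if (require_fl && any(is.na(base$fl)))
    stopf("baseline fatty-liver status missing for %d member(s); impute first",
          sum(is.na(base$fl)))
  base$ratio <- ldl_hdl_ratio(base$ldl, base$hdl)
  rownames(base) <- NULL
  base
}
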