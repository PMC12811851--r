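#' An empty cohort table
#'
#' Zero-row tibble with the full cohort schema; useful as a neutral element
#' for binds and for writing header-only CSVs.
#'
#' @return A zero-row cohort tibble.
#' @export
empty_cohort <- function() {
  records <- tibble::tibble(
    admission_id = character(), age_months = integer(), sex = character(),
    admission_date = as.Date(character()), outcome = character(),
    resp_rate = numeric(), spo2_percent = integer(),
    conscious_level = character(), muac_cm = numeric(), waz = numeric(),
    wlz = numeric()
  )
  for (s in sign_fields()) records[[s]] <- integer()
  records$alri_discharge_dx <- logical()
  records$severe_alri_presentation <- logical()
  records
}

#' Study-cohort inclusion specifications
#'
#' Returns the inclusion rules for one of the six analysis cohorts:
#' \describe{
#'   \item{A}{ages 2-24 months, ALRI discharge diagnosis required,
#'     complete cases only (the primary cohort).}
#'   \item{B}{as A but without the discharge-diagnosis requirement.}
#'   \item{C}{as A but ages 2-59 months.}
#'   \item{D}{as A but records with missing score components retained.}
#'   \item{E}{as A, excluding admissions during the first pandemic year
#'     (13 March 2020 to 13 March 2021, both ends inclusive).}
#'   \item{F}{as A, keeping only admissions strictly before 13 March 2020.}
#' }
#'
#' @param cohort_id One of `"A"` through `"F"`.
#' @return A `cohort_spec` list with fields `cohort_id`, `age_range_months`,
#'   `require_alri_dx`, `allow_missing`, `date_filter` (either `NULL`, a
#'   list `list(exclude_between = c(from, to))`, or
#'   `list(before = date)`).
#' @export
cohort_spec <- function(cohort_id = c("A", "B", "C", "D", "E", "F")) {
  cohort_id <- match.arg(cohort_id)
  pandemic_start <- as.Date("2020-03-13")
  spec <- switch(cohort_id,
    A = list(age_range_months = c(2L, 24L), require_alri_dx = TRUE,
             allow_missing = FALSE, date_filter = NULL),
    B = list(age_range_months = c(2L, 24L), require_alri_dx = FALSE,
             allow_missing = FALSE, date_filter = NULL),
    C = list(age_range_months = c(2L, 59L), require_alri_dx = TRUE,
             allow_missing = FALSE, date_filter = NULL),
    D = list(age_range_months = c(2L, 24L), require_alri_dx = TRUE,
             allow_missing = TRUE, date_filter = NULL),
    E = list(age_range_months = c(2L, 24L), require_alri_dx = TRUE,
             allow_missing = FALSE,
             date_filter = list(exclude_between = c(pandemic_start,
                                                    as.Date("2021-03-13")))),
    F = list(age_range_months = c(2L, 24L), require_alri_dx = TRUE,
             allow_missing = FALSE,
             date_filter = list(before = pandemic_start))
  )
  structure(c(list(cohort_id = cohort_id), spec), class = "cohort_spec")
}

exclusion_reasons <- c("age_out_of_range", "no_alri_dx", "missing_data",
                       "other_outcome", "date_excluded", "included")

#' Apply a cohort inclusion specification
#'
#' Filters a cohort table against a [cohort_spec()] and accounts for every
#' input record under exactly one reason, in the fixed precedence
#' age -> diagnosis -> missing data -> outcome -> date; a record is tallied
#' under the first criterion it fails. The tally always sums to the number
#' of input records.
#'
#' @param records Cohort tibble.
#' @param spec A `cohort_spec`.
#' @param required_fields Columns that must be non-missing for a complete
#'   case (ignored when the spec allows missing data). Typically
#'   [default_required_fields()].
#' @return A list with `included` (the filtered tibble) and `tally`
#'   (named integer vector over the exclusion reasons plus `included`).
#' @export
apply_cohort_filter <- function(records, spec,
                                required_fields = default_required_fields()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(records)
  tally <- stats::setNames(integer(length(exclusion_reasons)), exclusion_reasons)
  if (n == 0) {
    return(list(included = records, tally = tally))
  }
  unknown <- setdiff(required_fields, names(records))
  if (length(unknown) > 0) {
    stop("required_fields not present in cohort table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  reason <- rep(NA_character_, n)
  age_ok <- records$age_months >= spec$age_range_months[1] &
    records$age_months <= spec$age_range_months[2]
  reason[!age_ok] <- "age_out_of_range"

  if (spec$require_alri_dx) {
    fail <- is.na(reason) & !records$alri_discharge_dx
    reason[fail] <- "no_alri_dx"
  }
  if (!spec$allow_missing && length(required_fields) > 0) {
    any_missing <- Reduce(`|`, lapply(required_fields,
                                      function(f) is.na(records[[f]])))
    reason[is.na(reason) & any_missing] <- "missing_data"
  }
  fail <- is.na(reason) & !(records$outcome %in% c("died", "discharged"))
  reason[fail] <- "other_outcome"

  if (!is.null(spec$date_filter)) {
    d <- records$admission_date
    if (!is.null(spec$date_filter$exclude_between)) {
      win <- spec$date_filter$exclude_between
      date_fail <- d >= win[1] & d <= win[2]
    } else {
      date_fail <- d >= spec$date_filter$before
    }
    reason[is.na(reason) & date_fail] <- "date_excluded"
  }
  reason[is.na(reason)] <- "included"

  counts <- table(factor(reason, levels = exclusion_reasons))
  tally[] <- as.integer(counts)
  list(included = records[reason == "included", , drop = FALSE], tally = tally)
}
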