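#' alriscore: pediatric ALRI severity scores and their validation
#'
#' Declarative computation of point-based clinical severity scores from
#' admission records, discrimination analysis against in-hospital
#' mortality, descriptive statistics with crude and adjusted odds
#' ratios, and a seeded synthetic cohort generator.
#'
#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for admission records. Every sign flag is coded
## 1 (present) / 0 (absent) / NA (not assessed); all other categoricals are
## lower-case strings drawn from the sets below.

#' Clinical sign flags recorded at admission
#'
#' The binary sign vocabulary used throughout the package: each admission
#' carries one present/absent/missing flag per sign.
#'
#' @return Character vector of sign column names.
#' @export
sign_fields <- function() {
  c(
    "chest_indrawing", "convulsion", "cough", "crackles", "cyanosis",
    "decreased_skin_turgor", "deep_breathing", "diarrhea", "head_nodding",
    "nasal_flaring", "pallor", "sunken_eye", "vomiting", "vomits_everything",
    "unable_to_drink", "wheeze"
  )
}

sex_levels <- c("female", "male")
outcome_levels <- c("died", "discharged", "absconded", "transferred")
conscious_levels <- c("normal", "agitated", "lethargic", "prostrate", "unconscious")

#' Column order of a cohort table
#'
#' @return Character vector naming every column of an admission-cohort
#'   tibble, in canonical order.
#' @export
cohort_columns <- function() {
  c(
    "admission_id", "age_months", "sex", "admission_date", "outcome",
    "resp_rate", "spo2_percent", "conscious_level", "muac_cm", "waz", "wlz",
    sign_fields(), "alri_discharge_dx", "severe_alri_presentation"
  )
}

#' Validate an admission-cohort table
#'
#' Checks column presence, controlled vocabularies, and range invariants
#' (age 1-59 months, SpO2 0-100 when present, signs coded 0/1/NA). Errors
#' name the first offending row and column.
#'
#' @param records A cohort tibble as produced by [read_cohort_csv()] or
#'   [generate_cohort()].
#' @return The validated tibble, invisibly.
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_vocab <- function(col, levels, allow_na = FALSE) {
    x <- records[[col]]
    bad <- !(x %in% levels) & !(allow_na & is.na(x))
    if (any(bad)) {
      stop(sprintf("invalid value '%s' in column '%s' (row %d)",
                   as.character(x[which(bad)[1]]), col, which(bad)[1]),
           call. = FALSE)
    }
  }
  check_vocab("sex", sex_levels)
  check_vocab("outcome", outcome_levels)
  check_vocab("conscious_level", conscious_levels, allow_na = TRUE)
  for (s in sign_fields()) check_vocab(s, c(0L, 1L), allow_na = TRUE)

  age <- records$age_months
  if (any(is.na(age)) || any(age < 1 | age > 59)) {
    bad <- which(is.na(age) | age < 1 | age > 59)[1]
    stop(sprintf("age_months out of range 1-59 (row %d)", bad), call. = FALSE)
  }
  spo2 <- records$spo2_percent
  if (any(spo2 < 0 | spo2 > 100, na.rm = TRUE)) {
    bad <- which(spo2 < 0 | spo2 > 100)[1]
    stop(sprintf("spo2_percent out of range 0-100 (row %d)", bad), call. = FALSE)
  }
  if (any(is.na(records$outcome))) {
    stop(sprintf("outcome missing (row %d)", which(is.na(records$outcome))[1]),
         call. = FALSE)
  }
  invisible(records)
}

#' Read an admission cohort from CSV
#'
#' Expects a UTF-8 comma-separated file with one header row and the columns
#' of [cohort_columns()]; the literal string `NA` marks a missing value and
#' dates are ISO-8601. The result is validated against the controlled
#' vocabularies, with errors naming the offending row and column.
#'
#' @param path Path to a cohort CSV.
#' @return A tibble with one row per admission.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop(sprintf("unparseable numeric value '%s' in column '%s' (row %d)",
                   x[which(bad)[1]], col, which(bad)[1]), call. = FALSE)
    }
    out
  }
  int <- function(col) {
    x <- num(col)
    ifelse(is.na(x), NA_integer_, as.integer(x))
  }
  lgl <- function(col) {
    x <- raw[[col]]
    bad <- !is.na(x) & !(x %in% c("0", "1", "TRUE", "FALSE"))
    if (any(bad)) {
      stop(sprintf("unparseable logical value '%s' in column '%s' (row %d)",
                   x[which(bad)[1]], col, which(bad)[1]), call. = FALSE)
    }
    !is.na(x) & x %in% c("1", "TRUE")
  }
  records <- tibble::tibble(
    admission_id = raw$admission_id,
    age_months = int("age_months"),
    sex = raw$sex,
    admission_date = as.Date(raw$admission_date),
    outcome = raw$outcome,
    resp_rate = num("resp_rate"),
    spo2_percent = int("spo2_percent"),
    conscious_level = raw$conscious_level,
    muac_cm = num("muac_cm"),
    waz = num("waz"),
    wlz = num("wlz")
  )
  for (s in sign_fields()) records[[s]] <- int(s)
  records$alri_discharge_dx <- lgl("alri_discharge_dx")
  records$severe_alri_presentation <- lgl("severe_alri_presentation")
  validate_records(records)
  records
}

#' Write an admission cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: `NA` sentinels for missing values,
#' ISO-8601 dates, sign flags and diagnosis booleans as 1/0. The written
#' file round-trips: `read_cohort_csv(write_cohort_csv(x, p))` reproduces
#' `x` field for field.
#'
#' @param records A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  if (nrow(records) > 0) validate_records(records)
  out <- records[, cohort_columns()]
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$alri_discharge_dx <- as.integer(out$alri_discharge_dx)
  out$severe_alri_presentation <- as.integer(out$severe_alri_presentation)
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
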