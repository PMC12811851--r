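#' Classify mid-upper arm circumference
#'
#' WHO community-screening cutoffs for children 6-59 months, applied with a
#' strict less-than convention: severe malnutrition below 11.5 cm, moderate
#' from 11.5 up to (not including) 12.5 cm, normal at 12.5 cm and above.
#'
#' @param muac_cm Mid-upper arm circumference in centimetres (positive).
#' @return Character vector over `normal`, `moderate`, `severe`; `NA` in
#'   gives `NA` out.
#' @export
classify_muac <- function(muac_cm) {
  if (any(muac_cm <= 0, na.rm = TRUE)) {
    stop("muac_cm must be positive", call. = FALSE)
  }
  ifelse(is.na(muac_cm), NA_character_,
         ifelse(muac_cm < 11.5, "severe",
                ifelse(muac_cm < 12.5, "moderate", "normal")))
}

#' Classify a weight-based z-score
#'
#' Applies the WHO growth-standard thresholds to a weight-for-age or
#' weight-for-length z-score: severe below -3, moderate from -3 up to (not
#' including) -2, normal at -2 and above. Boundaries are strict: z = -2
#' exactly is normal.
#'
#' @param z Finite z-score.
#' @return Character vector over `normal`, `moderate`, `severe`; `NA` in
#'   gives `NA` out.
#' @export
classify_zscore <- function(z) {
  if (any(!is.finite(z) & !is.na(z))) {
    stop("z-score must be finite", call. = FALSE)
  }
  ifelse(is.na(z), NA_character_,
         ifelse(z < -3, "severe",
                ifelse(z < -2, "moderate", "normal")))
}

#' Categorize respiratory rate against the WHO fast-breathing cutoff
#'
#' The age-specific cutoff is 40 breaths/min for ages 2-11 months and
#' 50 breaths/min from 12 months upward. Rates are banded by their excess
#' over the cutoff: below the cutoff, 0-9 above, 10-19 above, or 20 and
#' more above.
#'
#' @param resp_rate Respiratory rate in breaths per minute (non-negative).
#' @param age_months Age in completed months, 2 or older.
#' @return Character vector over `below_cutoff`, `above_0_9`,
#'   `above_10_19`, `above_20_plus`; `NA` rate gives `NA`.
#' @export
respiratory_rate_category <- function(resp_rate, age_months) {
  if (any(age_months < 2, na.rm = TRUE)) {
    stop("respiratory rate cutoffs are unsupported below 2 months of age",
         call. = FALSE)
  }
  if (any(resp_rate < 0, na.rm = TRUE)) {
    stop("resp_rate must be non-negative", call. = FALSE)
  }
  cutoff <- ifelse(age_months < 12, 40, 50)
  excess <- resp_rate - cutoff
  ifelse(is.na(excess), NA_character_,
         ifelse(excess < 0, "below_cutoff",
                ifelse(excess < 10, "above_0_9",
                       ifelse(excess < 20, "above_10_19", "above_20_plus"))))
}

#' Age band of an admission
#'
#' Inclusive month bands matching the descriptive-table stratification:
#' 2-5, 6-12, 13-24, and 25-59 months.
#'
#' @param age_months Age in completed months, 2-59.
#' @return Character vector over `band_2_5`, `band_6_12`, `band_13_24`,
#'   `band_25_59`.
#' @export
age_band <- function(age_months) {
  if (any(age_months < 2 | age_months > 59, na.rm = TRUE)) {
    stop("age_months must be within 2-59", call. = FALSE)
  }
  ifelse(is.na(age_months), NA_character_,
         ifelse(age_months <= 5, "band_2_5",
                ifelse(age_months <= 12, "band_6_12",
                       ifelse(age_months <= 24, "band_13_24", "band_25_59"))))
}

#' Severity points for a malnutrition category
#'
#' The nutrition component added to the bronchiolitis severity score:
#' 0 points for normal nutrition, 2 for moderate malnutrition, 3 for
#' severe malnutrition, graded like the score's other symptom items.
#'
#' @param category Character vector over `normal`, `moderate`, `severe`.
#' @return Integer points.
#' @export
nutrition_points <- function(category) {
  pts <- c(normal = 0L, moderate = 2L, severe = 3L)
  bad <- !is.na(category) & !(category %in% names(pts))
  if (any(bad)) {
    stop("unknown nutrition category: ", category[which(bad)[1]], call. = FALSE)
  }
  out <- unname(pts[category])
  out[is.na(category)] <- NA_integer_
  out
}
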