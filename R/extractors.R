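## Component extractors: named, deterministic mappings from admission-record
## fields to the category vocabulary a score definition assigns points over.
## Each extractor is vectorized over a cohort tibble and returns NA for rows
## where any of its source fields is missing. The special extractor
## "unavailable" models score components that the dataset cannot assess at
## all: it always yields the single category "unavailable" (worth 0 points
## in every bundled definition) and never counts as missing.

.extractor_cache <- new.env(parent = emptyenv())

extractor_registry_build <- function() {
  sign_extractors <- lapply(sign_fields(), function(s) {
    list(
      categories = c("absent", "present"),
      fields = s,
      fn = function(records) {
        x <- records[[s]]
        ifelse(is.na(x), NA_character_, ifelse(x == 1L, "present", "absent"))
      }
    )
  })
  names(sign_extractors) <- paste0("sign:", sign_fields())

  c(sign_extractors, list(
    spo2_lt90 = list(
      categories = c("no", "yes"),
      fields = "spo2_percent",
      fn = function(records) {
        x <- records$spo2_percent
        ifelse(is.na(x), NA_character_, ifelse(x < 90, "yes", "no"))
      }
    ),
    spo2_band3 = list(
      categories = c("gt92", "s90_92", "lt90"),
      fields = "spo2_percent",
      fn = function(records) {
        x <- records$spo2_percent
        ifelse(is.na(x), NA_character_,
               ifelse(x < 90, "lt90", ifelse(x <= 92, "s90_92", "gt92")))
      }
    ),
    resp_rate_band = list(
      categories = c("below_cutoff", "above_0_9", "above_10_19", "above_20_plus"),
      fields = c("resp_rate", "age_months"),
      fn = function(records) {
        respiratory_rate_category(records$resp_rate, records$age_months)
      }
    ),
    muac_band = list(
      categories = c("normal", "moderate", "severe"),
      fields = "muac_cm",
      fn = function(records) classify_muac(records$muac_cm)
    ),
    waz_band = list(
      categories = c("normal", "moderate", "severe"),
      fields = "waz",
      fn = function(records) classify_zscore(records$waz)
    ),
    wlz_band = list(
      categories = c("normal", "moderate", "severe"),
      fields = "wlz",
      fn = function(records) classify_zscore(records$wlz)
    ),
    waz_lt_minus2 = list(
      categories = c("no", "yes"),
      fields = "waz",
      fn = function(records) {
        x <- records$waz
        ifelse(is.na(x), NA_character_, ifelse(x < -2, "yes", "no"))
      }
    ),
    age_2_11 = list(
      categories = c("no", "yes"),
      fields = "age_months",
      fn = function(records) {
        ifelse(records$age_months < 12, "yes", "no")
      }
    ),
    sex = list(
      categories = c("female", "male"),
      fields = "sex",
      fn = function(records) records$sex
    ),
    conscious_level = list(
      categories = conscious_levels,
      fields = "conscious_level",
      fn = function(records) records$conscious_level
    ),
    ## Graded bronchiolitis-severity items, reconstructed algorithmically
    ## from the recorded fields; presentations the record schema cannot
    ## distinguish from normal map to the lowest category.
    feeding_intolerance = list(
      categories = c("none", "severe"),
      fields = "unable_to_drink",
      fn = function(records) {
        x <- records$unable_to_drink
        ifelse(is.na(x), NA_character_, ifelse(x == 1L, "severe", "none"))
      }
    ),
    respiratory_difficulty = list(
      categories = c("none", "moderate", "severe"),
      fields = c("chest_indrawing", "deep_breathing", "head_nodding"),
      fn = function(records) {
        ci <- records$chest_indrawing
        db <- records$deep_breathing
        hn <- records$head_nodding
        ifelse(is.na(ci) | is.na(db) | is.na(hn), NA_character_,
               ifelse(db == 1L | hn == 1L, "severe",
                      ifelse(ci == 1L, "moderate", "none")))
      }
    ),
    resp_frequency_graded = list(
      categories = c("none", "mild", "moderate", "severe"),
      fields = c("resp_rate", "age_months"),
      fn = function(records) {
        band <- respiratory_rate_category(records$resp_rate, records$age_months)
        map <- c(below_cutoff = "none", above_0_9 = "mild",
                 above_10_19 = "moderate", above_20_plus = "severe")
        unname(map[band])
      }
    ),
    general_condition = list(
      categories = c("normal", "mild", "moderate", "severe"),
      fields = "conscious_level",
      fn = function(records) {
        map <- c(normal = "normal", agitated = "mild", lethargic = "moderate",
                 prostrate = "severe", unconscious = "severe")
        unname(map[records$conscious_level])
      }
    ),
    unavailable = list(
      categories = "unavailable",
      fields = character(),
      fn = function(records) rep("unavailable", nrow(records))
    )
  ))
}

extractor_registry <- function() {
  if (is.null(.extractor_cache$registry)) {
    .extractor_cache$registry <- extractor_registry_build()
  }
  .extractor_cache$registry
}

#' Names of the available component extractors
#'
#' @return Character vector of extractor names accepted in score
#'   definition files.
#' @export
extractor_names <- function() names(extractor_registry())

extract_categories <- function(records, extractor) {
  ex <- extractor_registry()[[extractor]]
  if (is.null(ex)) stop("unknown extractor: ", extractor, call. = FALSE)
  ex$fn(records)
}

extractor_categories <- function(extractor) {
  ex <- extractor_registry()[[extractor]]
  if (is.null(ex)) stop("unknown extractor: ", extractor, call. = FALSE)
  ex$categories
}

extractor_fields <- function(extractor) {
  ex <- extractor_registry()[[extractor]]
  if (is.null(ex)) stop("unknown extractor: ", extractor, call. = FALSE)
  ex$fields
}
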