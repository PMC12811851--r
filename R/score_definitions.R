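#' Path to the bundled score-definition file
#'
#' The package ships one JSON file describing all eight point-based
#' severity scores (components, category-to-point rules, theoretical
#' range, structurally unavailable components). The weights are
#' reconstructions from the original development publications of each
#' score, adapted to the admission-record fields this package models;
#' see the file's own `note` field and the methods vignette.
#'
#' @return File path of the packaged definition file.
#' @export
default_definitions_path <- function() {
  system.file("extdata", "score_definitions.json", package = "alriscore",
              mustWork = TRUE)
}

#' Load and validate score definitions
#'
#' Parses a score-definition JSON file into a registry (named list of
#' `score_definition` objects) and validates every definition: component
#' ids unique within a score, extractors known, every extractor category
#' assigned a point value (and no extras), `required_fields` nonempty,
#' declared theoretical min/max equal to the sums of per-component
#' minima/maxima, and `unavailable_components` a subset of component ids.
#' Validation failures name the offending score and component.
#'
#' @param config_path Path to a definition file; defaults to the bundled
#'   eight-score file.
#' @return Named list of `score_definition` objects, keyed by `score_id`.
#' @export
load_score_definitions <- function(config_path = default_definitions_path()) {
  doc <- jsonlite::read_json(config_path, simplifyVector = FALSE)
  if (is.null(doc$scores) || length(doc$scores) == 0) {
    stop("definition file contains no scores", call. = FALSE)
  }
  registry <- lapply(doc$scores, parse_score_definition)
  ids <- vapply(registry, function(d) d$score_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate score_id in definition file: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  names(registry) <- ids
  registry
}

parse_score_definition <- function(raw) {
  sid <- raw$score_id
  if (is.null(sid) || !nzchar(sid)) stop("score with empty score_id", call. = FALSE)
  comps <- lapply(raw$components, function(c_raw) {
    list(
      component_id = c_raw$component_id,
      extractor = c_raw$extractor,
      points = vapply(c_raw$points, function(p) as.integer(p), integer(1)),
      required_fields = vapply(c_raw$required_fields, as.character, character(1))
    )
  })
  def <- structure(
    list(
      score_id = sid,
      label = if (is.null(raw$label)) sid else raw$label,
      components = comps,
      theoretical_min = as.integer(raw$theoretical_min),
      theoretical_max = as.integer(raw$theoretical_max),
      unavailable_components = vapply(raw$unavailable_components,
                                      as.character, character(1))
    ),
    class = "score_definition"
  )
  validate_score_definition(def)
  def
}

validate_score_definition <- function(def) {
  sid <- def$score_id
  ids <- vapply(def$components, function(x) x$component_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("score '%s': duplicate component_id '%s'", sid,
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  for (comp in def$components) {
    cid <- comp$component_id
    if (!comp$extractor %in% extractor_names()) {
      stop(sprintf("score '%s', component '%s': unknown extractor '%s'",
                   sid, cid, comp$extractor), call. = FALSE)
    }
    cats <- extractor_categories(comp$extractor)
    missing_cat <- setdiff(cats, names(comp$points))
    if (length(missing_cat) > 0) {
      stop(sprintf("score '%s', component '%s': category '%s' has no point value",
                   sid, cid, missing_cat[1]), call. = FALSE)
    }
    extra <- setdiff(names(comp$points), cats)
    if (length(extra) > 0) {
      stop(sprintf("score '%s', component '%s': point value for unknown category '%s'",
                   sid, cid, extra[1]), call. = FALSE)
    }
    if (length(comp$required_fields) == 0) {
      stop(sprintf("score '%s', component '%s': required_fields is empty",
                   sid, cid), call. = FALSE)
    }
  }
  min_sum <- sum(vapply(def$components, function(x) min(x$points), integer(1)))
  max_sum <- sum(vapply(def$components, function(x) max(x$points), integer(1)))
  if (min_sum != def$theoretical_min || max_sum != def$theoretical_max) {
    stop(sprintf(
      "score '%s': declared range [%d, %d] does not match component sums [%d, %d]",
      sid, def$theoretical_min, def$theoretical_max, min_sum, max_sum),
      call. = FALSE)
  }
  bad <- setdiff(def$unavailable_components, ids)
  if (length(bad) > 0) {
    stop(sprintf("score '%s': unavailable component '%s' is not a component",
                 sid, bad[1]), call. = FALSE)
  }
  invisible(def)
}

#' Serialize a score-definition registry
#'
#' Writes a registry back to the JSON schema read by
#' [load_score_definitions()]; re-parsing the written file yields an
#' equal registry.
#'
#' @param registry Named list of `score_definition` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
serialize_score_definitions <- function(registry, path) {
  scores <- lapply(unname(registry), function(def) {
    list(
      score_id = def$score_id,
      label = def$label,
      components = lapply(def$components, function(comp) {
        list(
          component_id = comp$component_id,
          extractor = comp$extractor,
          points = as.list(comp$points),
          required_fields = as.list(comp$required_fields)
        )
      }),
      theoretical_min = def$theoretical_min,
      theoretical_max = def$theoretical_max,
      unavailable_components = as.list(def$unavailable_components)
    )
  })
  jsonlite::write_json(list(schema_version = 1L, scores = scores), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Record fields required to evaluate a set of scores
#'
#' Union of the record fields needed by every assessable component of
#' every score in the registry, plus the three malnutrition measures used
#' in the nutrition-augmented score comparison (`muac_cm`, `waz`, `wlz`).
#' This is the field list the complete-case cohort filter checks.
#'
#' @param registry A registry from [load_score_definitions()]; defaults to
#'   the bundled one.
#' @return Character vector of record column names.
#' @export
default_required_fields <- function(registry = load_score_definitions()) {
  fields <- unlist(lapply(registry, function(def) {
    unlist(lapply(def$components, function(comp) {
      if (comp$extractor == "unavailable") character() else comp$required_fields
    }))
  }))
  sort(unique(c(fields, "muac_cm", "waz", "wlz")))
}

#' Augment the bronchiolitis severity score with a nutrition component
#'
#' Builds the nutrition-modified definition from a base definition by
#' appending one malnutrition component (0 points normal, 2 moderate,
#' 3 severe) measured by MUAC, weight-for-age z-score, or
#' weight-for-length z-score.
#'
#' @param base_def The unmodified `score_definition` (normally the
#'   bundled `resvinet`).
#' @param nutrition_measure One of `"muac"`, `"waz"`, `"wlz"`.
#' @return A new `score_definition` with id
#'   `<base>_plus_<measure>` (the bundled `resvinet_modified` equals the
#'   MUAC variant up to its id and label).
#' @export
modified_resvinet_definition <- function(base_def,
                                         nutrition_measure = c("muac", "waz", "wlz")) {
  nutrition_measure <- match.arg(nutrition_measure)
  extractor <- switch(nutrition_measure, muac = "muac_band",
                      waz = "waz_band", wlz = "wlz_band")
  field <- switch(nutrition_measure, muac = "muac_cm", waz = "waz", wlz = "wlz")
  nutrition <- list(
    component_id = "nutrition",
    extractor = extractor,
    points = c(normal = 0L, moderate = 2L, severe = 3L),
    required_fields = field
  )
  def <- base_def
  def$score_id <- paste0(base_def$score_id, "_plus_", nutrition_measure)
  def$label <- paste0(base_def$label, " + Nutrition (", toupper(nutrition_measure), ")")
  def$components <- c(base_def$components, list(nutrition))
  def$theoretical_max <- base_def$theoretical_max + 3L
  validate_score_definition(def)
  def
}
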