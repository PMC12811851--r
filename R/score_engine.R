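## Generic evaluation of declarative point-based severity scores.

## Internal: per-record component points for one definition.
## Returns a list with `points` (n x k integer matrix, NA where the
## component's source fields are missing) and `component_ids`.
component_points <- function(records, definition) {
  k <- length(definition$components)
  n <- nrow(records)
  pts <- matrix(NA_integer_, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    comp <- definition$components[[j]]
    cat <- extract_categories(records, comp$extractor)
    p <- unname(comp$points[cat])
    pts[, j] <- ifelse(is.na(cat), NA_integer_, p)
  }
  colnames(pts) <- vapply(definition$components, function(x) x$component_id,
                          character(1))
  pts
}

#' Compute one severity score for one admission
#'
#' Determines each component's category through its extractor, maps it to
#' points, and sums. Components whose source fields are missing either
#' abort (`missing_policy = "fail"`, the complete-case default) or
#' contribute 0 points and are reported in `components_skipped_missing`
#' (`"skip"`, the semantics used when evaluating records with missing
#' data). Structurally unavailable components always contribute 0 and are
#' never treated as missing.
#'
#' @param record One-row cohort tibble.
#' @param definition A `score_definition`.
#' @param missing_policy `"fail"` or `"skip"`.
#' @return A `score_result` list: `score_id`, `total` (integer),
#'   `components_used`, `components_skipped_missing`.
#' @export
compute_score <- function(record, definition, missing_policy = c("fail", "skip")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(nrow(record) == 1)
  pts <- component_points(record, definition)
  miss <- is.na(pts[1, ])
  if (any(miss) && missing_policy == "fail") {
    comp <- definition$components[[which(miss)[1]]]
    fields <- comp$required_fields
    absent <- fields[vapply(fields, function(f) {
      f %in% names(record) && is.na(record[[f]][1])
    }, logical(1))]
    stop(sprintf("score '%s': component '%s' has missing field(s): %s",
                 definition$score_id, comp$component_id,
                 paste(if (length(absent)) absent else fields, collapse = ", ")),
         call. = FALSE)
  }
  total <- sum(pts[1, !miss])
  structure(
    list(
      score_id = definition$score_id,
      total = as.integer(total),
      components_used = colnames(pts)[!miss],
      components_skipped_missing = colnames(pts)[miss]
    ),
    class = "score_result"
  )
}

## Internal: vectorized totals for one definition over a whole cohort.
compute_score_totals <- function(records, definition,
                                 missing_policy = c("fail", "skip")) {
  missing_policy <- match.arg(missing_policy)
  pts <- component_points(records, definition)
  if (missing_policy == "fail" && anyNA(pts)) {
    bad <- which(rowSums(is.na(pts)) > 0)[1]
    comp <- colnames(pts)[which(is.na(pts[bad, ]))[1]]
    id <- records$admission_id[bad]
    stop(sprintf("score '%s': admission '%s' has missing data for component '%s'",
                 definition$score_id, id, comp), call. = FALSE)
  }
  as.integer(rowSums(pts, na.rm = TRUE))
}

#' Compute all scores for a cohort
#'
#' One integer total per admission per score, in input order.
#'
#' @param records Cohort tibble.
#' @param registry Score registry from [load_score_definitions()].
#' @param missing_policy Passed to each score evaluation; see
#'   [compute_score()].
#' @return Tibble with `admission_id` plus one column of totals per
#'   `score_id` in the registry.
#' @export
compute_score_matrix <- function(records, registry = load_score_definitions(),
                                 missing_policy = c("fail", "skip")) {
  missing_policy <- match.arg(missing_policy)
  out <- tibble::tibble(admission_id = records$admission_id)
  for (def in registry) {
    out[[def$score_id]] <- compute_score_totals(records, def, missing_policy)
  }
  out
}

#' Nutrition-modified bronchiolitis severity score for one admission
#'
#' Evaluates the base ReSVinet-style definition and adds the malnutrition
#' points (0 normal / 2 moderate / 3 severe) of the chosen measure. The
#' chosen measure must be present for the record; the three variants
#' differ only in their nutrition component.
#'
#' @param record One-row cohort tibble.
#' @param nutrition_measure `"muac"`, `"waz"`, or `"wlz"`.
#' @param registry Score registry providing the base `resvinet`
#'   definition.
#' @param missing_policy Policy for the base components.
#' @return A `score_result`, as [compute_score()].
#' @export
compute_modified_resvinet <- function(record,
                                      nutrition_measure = c("muac", "waz", "wlz"),
                                      registry = load_score_definitions(),
                                      missing_policy = c("fail", "skip")) {
  nutrition_measure <- match.arg(nutrition_measure)
  missing_policy <- match.arg(missing_policy)
  field <- switch(nutrition_measure, muac = "muac_cm", waz = "waz", wlz = "wlz")
  if (is.na(record[[field]][1])) {
    stop(sprintf("modified score requires nutrition measure '%s' but field '%s' is missing",
                 nutrition_measure, field), call. = FALSE)
  }
  def <- modified_resvinet_definition(registry$resvinet, nutrition_measure)
  compute_score(record, def, missing_policy)
}
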