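registry <- load_score_definitions()

test_that("the bundled definition file loads all eight scores", {
  expect_length(registry, 8)
  expect_setequal(names(registry),
                  c("risc_hivneg", "mrisc", "risc_malawi_muac",
                    "risc_malawi_waz", "perch", "prepare", "resvinet",
                    "resvinet_modified"))
  for (def in registry) {
    expect_s3_class(def, "score_definition")
    expect_lte(def$theoretical_min, def$theoretical_max)
  }
})

test_that("definition schema violations are rejected with the offender named", {
  base <- jsonlite::read_json(default_definitions_path(), simplifyVector = FALSE)
  write_doc <- function(doc) {
    path <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
    jsonlite::write_json(doc, path, auto_unbox = TRUE)
    path
  }
  # drop a point value for one category
  doc <- base
  doc$scores[[1]]$components[[1]]$points$yes <- NULL
  expect_error(load_score_definitions(write_doc(doc)),
               "category 'yes' has no point value")
  # break the declared range
  doc <- base
  doc$scores[[1]]$theoretical_max <- 99
  expect_error(load_score_definitions(write_doc(doc)), "does not match")
  # duplicate a component id
  doc <- base
  doc$scores[[1]]$components[[2]]$component_id <-
    doc$scores[[1]]$components[[1]]$component_id
  expect_error(load_score_definitions(write_doc(doc)), "duplicate component_id")
})

test_that("serializing a registry reparses to an equal registry", {
  path <- withr::local_tempfile(fileext = ".json")
  serialize_score_definitions(registry, path)
  expect_equal(load_score_definitions(path), registry)
})

test_that("an all-reference presentation scores 0 on every bundled score", {
  # 18-month-old male: also at reference for the age and sex components
  rec <- make_record(age_months = 18L, sex = "male")
  for (def in registry) {
    expect_identical(compute_score(rec, def)$total, 0L, info = def$score_id)
  }
})

test_that("changing one component moves the total by that component's point gap", {
  def <- registry$risc_malawi_muac
  gap <- local({
    comp <- Filter(function(x) x$component_id == "malnutrition_muac",
                   def$components)[[1]]
    comp$points[["severe"]] - comp$points[["normal"]]
  })
  severe <- compute_score(make_record(muac_cm = 11.0), def)$total
  normal <- compute_score(make_record(muac_cm = 13.0), def)$total
  expect_identical(severe - normal, gap)
})

test_that("missing fields obey the skip/fail policy contract", {
  rec <- make_record(spo2_percent = NA_integer_)
  def <- registry$risc_hivneg
  expect_error(compute_score(rec, def, "fail"), "hypoxaemia.*spo2_percent")
  skipped <- compute_score(rec, def, "skip")
  expect_identical(skipped$components_skipped_missing, "hypoxaemia")
  expect_false("hypoxaemia" %in% skipped$components_used)

  # with complete data the two policies agree exactly
  coh <- make_cohort(50, seed = 3L)
  for (def in registry) {
    expect_identical(compute_score_matrix(coh, registry["risc_hivneg"], "fail"),
                     compute_score_matrix(coh, registry["risc_hivneg"], "skip"))
  }
})

test_that("totals are additive over components and bounded by the declared range", {
  coh <- make_cohort(120, seed = 8L)
  for (def in registry) {
    for (i in sample(nrow(coh), 15)) {
      res <- compute_score(coh[i, ], def)
      # independent per-component recount from the definition file
      pts <- vapply(def$components, function(comp) {
        cat <- extract_categories <- NULL
        row <- coh[i, ]
        category <- switch(comp$extractor,
          "spo2_lt90" = if (row$spo2_percent < 90) "yes" else "no",
          "spo2_band3" = if (row$spo2_percent < 90) "lt90" else if (row$spo2_percent <= 92) "s90_92" else "gt92",
          "resp_rate_band" = respiratory_rate_category(row$resp_rate, row$age_months),
          "muac_band" = classify_muac(row$muac_cm),
          "waz_band" = classify_zscore(row$waz),
          "wlz_band" = classify_zscore(row$wlz),
          "waz_lt_minus2" = if (row$waz < -2) "yes" else "no",
          "age_2_11" = if (row$age_months < 12) "yes" else "no",
          "sex" = row$sex,
          "conscious_level" = row$conscious_level,
          "feeding_intolerance" = if (row$unable_to_drink == 1) "severe" else "none",
          "respiratory_difficulty" = if (row$deep_breathing == 1 || row$head_nodding == 1) "severe" else if (row$chest_indrawing == 1) "moderate" else "none",
          "resp_frequency_graded" = c(below_cutoff = "none", above_0_9 = "mild",
                                      above_10_19 = "moderate",
                                      above_20_plus = "severe")[[respiratory_rate_category(row$resp_rate, row$age_months)]],
          "general_condition" = c(normal = "normal", agitated = "mild",
                                  lethargic = "moderate", prostrate = "severe",
                                  unconscious = "severe")[[row$conscious_level]],
          "unavailable" = "unavailable",
          {
            flag <- sub("^sign:", "", comp$extractor)
            if (row[[flag]] == 1) "present" else "absent"
          })
        comp$points[[category]]
      }, integer(1))
      expect_identical(res$total, sum(pts), info = def$score_id)
      expect_gte(res$total, def$theoretical_min)
      expect_lte(res$total, def$theoretical_max)
    }
  }
})

test_that("the nutrition modification decomposes as base plus nutrition points", {
  coh <- make_cohort(60, seed = 12L)
  for (i in seq_len(20)) {
    rec <- coh[i, ]
    base <- compute_score(rec, registry$resvinet)$total
    for (measure in c("muac", "waz", "wlz")) {
      mod <- compute_modified_resvinet(rec, measure, registry)$total
      category <- switch(measure,
                         muac = classify_muac(rec$muac_cm),
                         waz = classify_zscore(rec$waz),
                         wlz = classify_zscore(rec$wlz))
      expect_identical(mod - base, as.integer(nutrition_points(category)))
      expect_true((mod - base) %in% c(0L, 2L, 3L))
    }
  }
  # normal nutrition leaves the score unchanged
  rec <- make_record(muac_cm = 14)
  expect_identical(compute_modified_resvinet(rec, "muac", registry)$total,
                   compute_score(rec, registry$resvinet)$total)
  # published point assignments: severe +3, moderate +2
  base <- compute_score(make_record(), registry$resvinet)$total
  expect_identical(
    compute_modified_resvinet(make_record(muac_cm = 11.0), "muac", registry)$total,
    base + 3L)
  expect_identical(
    compute_modified_resvinet(make_record(waz = -2.5), "waz", registry)$total,
    base + 2L)
  expect_error(
    compute_modified_resvinet(make_record(muac_cm = NA_real_), "muac", registry),
    "missing")
})

test_that("the bundled modified definition equals the on-the-fly MUAC variant", {
  built <- modified_resvinet_definition(registry$resvinet, "muac")
  bundled <- registry$resvinet_modified
  expect_equal(built$components, bundled$components)
  expect_identical(built$theoretical_max, bundled$theoretical_max)
})

test_that("the score matrix is order-equivariant and complete", {
  coh <- make_cohort(40, seed = 21L)
  m <- compute_score_matrix(coh, registry)
  expect_identical(dim(m), c(40L, 9L))
  perm <- sample(nrow(coh))
  m_perm <- compute_score_matrix(coh[perm, ], registry)
  expect_equal(m_perm, m[perm, ])
  diffs <- m$resvinet_modified - m$resvinet
  expect_true(all(diffs %in% c(0L, 2L, 3L)))
})
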