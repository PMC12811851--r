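## Seeded synthetic admission cohorts.
##
## Covariates are drawn independently per variable from configured
## category prevalences; continuous measurements are then drawn uniformly
## within the chosen category's band, so categorization recovers the
## sampled category exactly. The outcome is Bernoulli from a logistic
## model that is linear in the sampled categories, with the intercept
## calibrated by bisection so the expected case fatality rate over the
## generated covariates hits the configured target. Generator
## coefficients are therefore exactly the conditional (adjusted) odds
## ratios the descriptive machinery should recover.

#' Build a synthetic-cohort generator configuration
#'
#' @param n_admissions Number of admissions to generate.
#' @param category_prevalences Named list: for each multi-category
#'   variable (`age_band`, `sex`, `resp_rate_cat`, `muac_cat`, `waz_cat`,
#'   `wlz_cat`, `conscious_level`, `spo2_cat`) a named probability vector
#'   summing to 1; for each sign, a single probability of the sign being
#'   present.
#' @param outcome_coef Named numeric vector of log-odds coefficients
#'   keyed `"variable=category"` (e.g. `"muac_cat=severe"`); omitted
#'   categories have coefficient 0.
#' @param target_cfr Expected in-hospital case fatality rate the
#'   intercept is calibrated to (strictly between 0 and 1).
#' @param date_range Two dates admissions are drawn uniformly between.
#' @param missingness_rates Named numeric vector of per-field
#'   missing-completely-at-random rates applied after generation.
#' @param p_alri_dx Probability of an ALRI discharge diagnosis flag.
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_admissions,
                             category_prevalences = table1_prevalences(),
                             outcome_coef = table1_outcome_coef(),
                             target_cfr = 0.07,
                             date_range = as.Date(c("2015-01-01", "2024-12-31")),
                             missingness_rates = numeric(),
                             p_alri_dx = 1.0,
                             seed = 1L) {
  stopifnot(n_admissions >= 1)
  if (!(target_cfr > 0 && target_cfr < 1)) {
    stop("target_cfr must lie strictly between 0 and 1", call. = FALSE)
  }
  for (v in names(category_prevalences)) {
    p <- category_prevalences[[v]]
    if (length(p) > 1 && abs(sum(p) - 1) > 1e-6) {
      stop(sprintf("prevalences for '%s' must sum to 1", v), call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop(sprintf("prevalences for '%s' must lie in [0, 1]", v), call. = FALSE)
    }
  }
  structure(
    list(n_admissions = as.integer(n_admissions),
         category_prevalences = category_prevalences,
         outcome_coef = outcome_coef,
         target_cfr = target_cfr,
         date_range = as.Date(date_range),
         missingness_rates = missingness_rates,
         p_alri_dx = p_alri_dx,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Default category prevalences emulating the published cohort margins
#'
#' Overall category percentages of the 2182-admission Kilifi cohort,
#' normalized to probabilities. Only the margins are emulated; covariate
#' blocks are sampled independently.
#'
#' @return Named list of prevalence vectors, see [generator_config()].
#' @export
table1_prevalences <- function() {
  norm <- function(x) x / sum(x)
  list(
    age_band = norm(c(band_2_5 = 0.396, band_6_12 = 0.351, band_13_24 = 0.253)),
    sex = norm(c(female = 0.428, male = 0.572)),
    resp_rate_cat = norm(c(below_cutoff = 0.348, above_0_9 = 0.283,
                           above_10_19 = 0.213, above_20_plus = 0.156)),
    muac_cat = norm(c(normal = 0.603, moderate = 0.184, severe = 0.213)),
    waz_cat = norm(c(normal = 0.646, moderate = 0.192, severe = 0.162)),
    wlz_cat = norm(c(normal = 0.808, moderate = 0.137, severe = 0.055)),
    conscious_level = norm(c(normal = 0.725, agitated = 0.031,
                             lethargic = 0.154, prostrate = 0.075,
                             unconscious = 0.016)),
    spo2_cat = norm(c(gt92 = 0.815, s90_92 = 0.055, lt90 = 0.130)),
    chest_indrawing = 0.983, convulsion = 0.041, cough = 0.941,
    crackles = 0.519, cyanosis = 0.013, decreased_skin_turgor = 0.017,
    deep_breathing = 0.220, diarrhea = 0.142, head_nodding = 0.172,
    nasal_flaring = 0.656, pallor = 0.177, sunken_eye = 0.038,
    vomiting = 0.199, vomits_everything = 0.058, unable_to_drink = 0.112,
    wheeze = 0.170
  )
}

#' Default outcome coefficients from the published adjusted odds ratios
#'
#' Log-odds coefficients set to the logs of the published age/sex-adjusted
#' odds ratios of the Kilifi cohort, giving a realistic (margins-only)
#' mortality model over the generated covariates.
#'
#' @return Named numeric vector keyed `"variable=category"`.
#' @export
table1_outcome_coef <- function() {
  log(c(
    "age_band=band_6_12" = 0.6, "age_band=band_13_24" = 0.5,
    "sex=male" = 0.7,
    "resp_rate_cat=above_0_9" = 1.0, "resp_rate_cat=above_10_19" = 1.1,
    "resp_rate_cat=above_20_plus" = 2.3,
    "muac_cat=moderate" = 2.6, "muac_cat=severe" = 7.4,
    "conscious_level=agitated" = 7.1, "conscious_level=lethargic" = 2.8,
    "conscious_level=prostrate" = 7.3, "conscious_level=unconscious" = 19.4,
    "spo2_cat=s90_92" = 1.5, "spo2_cat=lt90" = 6.4,
    "deep_breathing=present" = 3.4, "pallor=present" = 3.6,
    "unable_to_drink=present" = 3.2, "wheeze=present" = 0.7
  ))
}

## Internal: draw the covariate block (everything except outcome), plus
## the linear predictor of the outcome model (without intercept).
generate_covariates <- function(config, n) {
  prev <- config$category_prevalences
  draw_cat <- function(v) {
    p <- prev[[v]]
    sample(names(p), n, replace = TRUE, prob = p)
  }
  age_b <- draw_cat("age_band")
  age_months <- integer(n)
  for (b in unique(age_b)) {
    idx <- age_b == b
    rng <- switch(b, band_2_5 = 2:5, band_6_12 = 6:12,
                  band_13_24 = 13:24, band_25_59 = 25:59)
    age_months[idx] <- sample(rng, sum(idx), replace = TRUE)
  }
  sex <- draw_cat("sex")
  rr_cat <- draw_cat("resp_rate_cat")
  cutoff <- ifelse(age_months < 12, 40, 50)
  offset <- integer(n)
  for (b in unique(rr_cat)) {
    idx <- rr_cat == b
    rng <- switch(b, below_cutoff = -15:-1, above_0_9 = 0:9,
                  above_10_19 = 10:19, above_20_plus = 20:40)
    offset[idx] <- sample(rng, sum(idx), replace = TRUE)
  }
  resp_rate <- cutoff + offset

  muac_cat <- draw_cat("muac_cat")
  muac <- numeric(n)
  for (b in unique(muac_cat)) {
    idx <- muac_cat == b
    lim <- switch(b, severe = c(9, 11.5), moderate = c(11.5, 12.5),
                  normal = c(12.5, 16))
    muac[idx] <- stats::runif(sum(idx), lim[1], lim[2])
  }
  draw_z <- function(zcat) {
    z <- numeric(n)
    for (b in unique(zcat)) {
      idx <- zcat == b
      lim <- switch(b, severe = c(-5, -3), moderate = c(-3, -2),
                    normal = c(-2, 1.5))
      z[idx] <- stats::runif(sum(idx), lim[1], lim[2])
    }
    z
  }
  waz_cat <- draw_cat("waz_cat")
  waz <- draw_z(waz_cat)
  wlz_cat <- draw_cat("wlz_cat")
  wlz <- draw_z(wlz_cat)

  conscious <- draw_cat("conscious_level")
  spo2_cat <- draw_cat("spo2_cat")
  spo2 <- integer(n)
  for (b in unique(spo2_cat)) {
    idx <- spo2_cat == b
    rng <- switch(b, gt92 = 93:100, s90_92 = 90:92, lt90 = 70:89)
    spo2[idx] <- sample(rng, sum(idx), replace = TRUE)
  }

  records <- tibble::tibble(
    admission_id = sprintf("SYN%06d", seq_len(n)),
    age_months = age_months,
    sex = sex,
    admission_date = config$date_range[1] +
      sample.int(as.integer(config$date_range[2] - config$date_range[1]) + 1L,
                 n, replace = TRUE) - 1L,
    outcome = rep("discharged", n),
    resp_rate = as.numeric(resp_rate),
    spo2_percent = spo2,
    conscious_level = conscious,
    muac_cm = muac,
    waz = waz,
    wlz = wlz
  )
  for (s in sign_fields()) {
    records[[s]] <- as.integer(stats::runif(n) < prev[[s]])
  }
  records$alri_discharge_dx <- stats::runif(n) < config$p_alri_dx
  records$severe_alri_presentation <- rep(TRUE, n)

  cat_values <- list(age_band = age_b, sex = sex, resp_rate_cat = rr_cat,
                     muac_cat = muac_cat, waz_cat = waz_cat,
                     wlz_cat = wlz_cat, conscious_level = conscious,
                     spo2_cat = spo2_cat)
  lp <- numeric(n)
  for (key in names(config$outcome_coef)) {
    parts <- strsplit(key, "=", fixed = TRUE)[[1]]
    v <- parts[1]
    lv <- parts[2]
    ind <- if (v %in% names(cat_values)) {
      cat_values[[v]] == lv
    } else if (v %in% sign_fields() && lv == "present") {
      records[[v]] == 1L
    } else {
      stop("outcome_coef key does not match a generated category: ", key,
           call. = FALSE)
    }
    lp <- lp + config$outcome_coef[[key]] * ind
  }
  list(records = records, lp = lp)
}

## Internal: intercept solving mean(plogis(a + lp)) = target by bisection.
calibrate_intercept <- function(lp, target_cfr, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + lp)) - target_cfr
  lo <- -40
  hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target_cfr is not attainable with the given coefficients",
         call. = FALSE)
  }
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < tol) return(mid)
  }
  (lo + hi) / 2
}

#' Generate a synthetic admission cohort
#'
#' Draws covariates from the configured prevalences, calibrates the
#' outcome-model intercept to the target case fatality rate by bisection
#' over the generated covariate distribution, draws died/discharged
#' outcomes from the logistic model, and injects
#' missing-completely-at-random values at the configured per-field rates.
#' Fully reproducible from the configuration.
#'
#' @param config A [generator_config()].
#' @return A validated cohort tibble of `n_admissions` rows.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  gen <- generate_covariates(config, config$n_admissions)
  a <- calibrate_intercept(gen$lp, config$target_cfr)
  p <- stats::plogis(a + gen$lp)
  records <- gen$records
  records$outcome <- ifelse(stats::runif(length(p)) < p, "died", "discharged")
  for (f in names(config$missingness_rates)) {
    rate <- config$missingness_rates[[f]]
    if (rate > 0) {
      records[[f]][stats::runif(nrow(records)) < rate] <- NA
    }
  }
  validate_records(records)
  records
}

#' Deterministic fixture reproducing the inclusion flow chart
#'
#' A 2261-admission cohort of 2-24-month-olds with severe ALRI
#' presentations and ALRI discharge diagnoses in which exactly 60 records
#' have missing score fields (4 missing both weight-derived z-scores, 16
#' missing weight-for-age only, 38 missing weight-for-length only, 2
#' missing the vomits-everything flag), exactly 19 have a non-death,
#' non-discharge outcome (5 absconded, 14 transferred), and exactly 152
#' of the remaining 2182 complete died/discharged records are deaths
#' (case fatality 7.0%). Outcomes follow the generator's logistic model,
#' with the death count pinned by flipping the records nearest the
#' decision boundary.
#'
#' @param seed Integer seed.
#' @return A cohort tibble of 2261 rows.
#' @export
generate_flowchart_fixture <- function(seed = 20150101L) {
  config <- generator_config(n_admissions = 2261L, seed = seed)
  records <- generate_cohort(config)

  # recompute model probabilities for the death-count adjustment
  set.seed(config$seed)
  gen <- generate_covariates(config, config$n_admissions)
  a <- calibrate_intercept(gen$lp, config$target_cfr)
  p <- stats::plogis(a + gen$lp)

  records$waz[1:4] <- NA
  records$wlz[1:4] <- NA
  records$waz[5:20] <- NA
  records$wlz[21:58] <- NA
  records$vomits_everything[59:60] <- NA
  records$outcome[61:65] <- "absconded"
  records$outcome[66:79] <- "transferred"

  included <- 80:2261
  died <- records$outcome[included] == "died"
  excess <- sum(died) - 152L
  if (excess > 0) {
    flip <- included[died][order(p[included][died])][seq_len(excess)]
    records$outcome[flip] <- "discharged"
  } else if (excess < 0) {
    flip <- included[!died][order(-p[included][!died])][seq_len(-excess)]
    records$outcome[flip] <- "died"
  }
  records
}

#' Model-implied AUROC of a score under a generator configuration
#'
#' Monte-Carlo oracle for the discrimination machinery: draws `n_mc`
#' covariate vectors (seeded from the configuration), computes the named
#' score's totals and each record's model death probability, and
#' evaluates the implied AUROC exactly over the outcome distribution
#' (probability-weighted pair comparison with ties counted 1/2) rather
#' than by drawing outcomes.
#'
#' @param config A [generator_config()].
#' @param score_id A score id present in `registry`.
#' @param registry Score registry.
#' @param n_mc Number of Monte-Carlo covariate draws.
#' @return The implied AUROC, a fraction in `[0, 1]`.
#' @export
model_implied_auroc <- function(config, score_id,
                                registry = load_score_definitions(),
                                n_mc = 100000L) {
  def <- registry[[score_id]]
  if (is.null(def)) stop("unknown score_id: ", score_id, call. = FALSE)
  set.seed(config$seed)
  gen <- generate_covariates(config, as.integer(n_mc))
  a <- calibrate_intercept(gen$lp, config$target_cfr)
  p <- stats::plogis(a + gen$lp)
  s <- compute_score_totals(gen$records, def, missing_policy = "fail")
  w1 <- tapply(p, s, sum)
  w0 <- tapply(1 - p, s, sum)
  if (sum(w1) == 0 || sum(w0) == 0) {
    stop("degenerate outcome distribution", call. = FALSE)
  }
  # scores ascend in tapply output; pairs where the death scores higher
  cum_w0 <- cumsum(w0) - w0
  (sum(w1 * cum_w0) + 0.5 * sum(w1 * w0)) / (sum(w1) * sum(w0))
}
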