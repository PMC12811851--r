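#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with a Woolf (log-scale normal) confidence
#' interval: `exp(log(ad/bc) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Cells are exposed deaths `a`, exposed discharges `b`, reference deaths
#' `c`, reference discharges `d`. A zero cell is an error unless the
#' Haldane-Anscombe +0.5 correction is explicitly requested.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param level Confidence level (default 0.95).
#' @param haldane Apply the +0.5 continuity correction to all cells when
#'   any cell is zero (default `FALSE`: fail loudly).
#' @param exposure_label,reference_label Labels carried into the result.
#' @return An `or_estimate` list: `odds_ratio`, `ci_low`, `ci_high`,
#'   `kind = "crude"`, `exposure_label`, `reference_label`.
#' @export
crude_or <- function(a, b, c, d, level = 0.95, haldane = FALSE,
                     exposure_label = "exposed", reference_label = "reference") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty 2x2 table", call. = FALSE)
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; set haldane = TRUE to apply the +0.5 correction",
           call. = FALSE)
    }
    cells <- cells + 0.5
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(odds_ratio = unname(or),
         ci_low = unname(exp(log(or) - z * se)),
         ci_high = unname(exp(log(or) + z * se)),
         kind = "crude",
         exposure_label = exposure_label,
         reference_label = reference_label),
    class = "or_estimate"
  )
}

## Derived categorical view of a cohort used by the descriptive table and
## the regression adjustments.
table1_variables <- function() {
  c("age_band", "sex", "resp_rate_cat", "muac_cat", "waz_cat", "wlz_cat",
    "conscious_level", "spo2_cat", sign_fields())
}

table1_reference <- function(variable) {
  refs <- c(age_band = "band_2_5", sex = "female",
            resp_rate_cat = "below_cutoff", muac_cat = "normal",
            waz_cat = "normal", wlz_cat = "normal",
            conscious_level = "normal", spo2_cat = "gt92")
  if (variable %in% names(refs)) unname(refs[variable]) else "absent"
}

#' Categorize a cohort into the descriptive-table variables
#'
#' Derives the categorical view used for descriptive statistics and
#' adjusted models: age band, respiratory-rate band relative to the WHO
#' cutoff, MUAC and z-score malnutrition bands, oxygen-saturation band,
#' and present/absent sign labels.
#'
#' @param records Cohort tibble.
#' @return Tibble of character columns, one per [table1_variables()],
#'   plus `outcome`.
#' @export
table1_categories <- function(records) {
  out <- tibble::tibble(
    age_band = age_band(records$age_months),
    sex = records$sex,
    resp_rate_cat = respiratory_rate_category(records$resp_rate,
                                              records$age_months),
    muac_cat = classify_muac(records$muac_cm),
    waz_cat = classify_zscore(records$waz),
    wlz_cat = classify_zscore(records$wlz),
    conscious_level = records$conscious_level,
    spo2_cat = {
      x <- records$spo2_percent
      ifelse(is.na(x), NA_character_,
             ifelse(x < 90, "lt90", ifelse(x <= 92, "s90_92", "gt92")))
    }
  )
  for (s in sign_fields()) {
    out[[s]] <- ifelse(is.na(records[[s]]), NA_character_,
                       ifelse(records[[s]] == 1L, "present", "absent"))
  }
  out$outcome <- records$outcome
  out
}

#' Crude odds ratios for each category of one variable
#'
#' One cross-product odds ratio per non-reference category against the
#' reference, each computed from only the records in those two
#' categories.
#'
#' @param records Cohort tibble (outcomes must be died/discharged).
#' @param variable One of [table1_variables()].
#' @param reference_category Reference level; defaults to the
#'   conventional reference of the variable.
#' @param haldane Passed to [crude_or()].
#' @return List of `or_estimate` objects, one per non-reference category
#'   (in order of appearance).
#' @export
categorical_or <- function(records, variable,
                           reference_category = table1_reference(variable),
                           haldane = FALSE) {
  cats <- table1_categories(records)
  if (!variable %in% names(cats)) {
    stop("unknown descriptive variable: ", variable, call. = FALSE)
  }
  x <- cats[[variable]]
  died <- cats$outcome == "died"
  keep <- !is.na(x)
  x <- x[keep]
  died <- died[keep]
  levels_ <- unique(x)
  if (length(levels_) < 2) {
    stop(sprintf("variable '%s' is constant; no comparison possible", variable),
         call. = FALSE)
  }
  if (!reference_category %in% levels_) {
    stop(sprintf("reference category '%s' is empty for variable '%s'",
                 reference_category, variable), call. = FALSE)
  }
  c_ref <- sum(died[x == reference_category])
  d_ref <- sum(!died[x == reference_category])
  lapply(setdiff(levels_, reference_category), function(lv) {
    crude_or(a = sum(died[x == lv]), b = sum(!died[x == lv]),
             c = c_ref, d = d_ref, haldane = haldane,
             exposure_label = lv, reference_label = reference_category)
  })
}

#' Maximum-likelihood logistic regression for mortality
#'
#' Fits `P(died) ~ covariates` by iteratively reweighted least squares
#' (convergence when the deviance change falls below 1e-8, at most 25
#' iterations). Categorical covariates are expanded against declared
#' reference levels. Rank-deficient designs error naming the collinear
#' columns; complete separation is detected and reported as a distinct
#' failure; constant covariates are dropped with a warning.
#'
#' @param records Cohort tibble with died/discharged outcomes.
#' @param covariates Character vector of covariate names: any of
#'   [table1_variables()] (categorized automatically) or raw numeric
#'   record columns.
#' @param references Named list of reference levels overriding the
#'   conventional references.
#' @return Tibble with columns `term`, `estimate`, `std_error`, and
#'   attributes `loglik`, `converged`, `iterations`, `dropped`
#'   (constant covariates removed).
#' @export
fit_logistic <- function(records, covariates, references = list()) {
  y <- records$outcome == "died"
  if (all(y) || !any(y)) {
    stop("both outcome classes are required to fit", call. = FALSE)
  }
  cats <- table1_categories(records)
  dat <- data.frame(y = y)
  dropped <- character()
  for (v in covariates) {
    col <- if (v %in% names(cats)) cats[[v]] else records[[v]]
    if (is.null(col)) stop("unknown covariate: ", v, call. = FALSE)
    if (anyNA(col)) stop("covariate '", v, "' has missing values", call. = FALSE)
    if (is.character(col)) {
      ref <- if (v %in% names(references)) references[[v]] else table1_reference(v)
      lev <- unique(col)
      if (length(lev) < 2) {
        warning("dropping constant covariate '", v, "'", call. = FALSE)
        dropped <- c(dropped, v)
        next
      }
      col <- factor(col, levels = c(ref, sort(setdiff(lev, ref))))
    } else if (length(unique(col)) < 2) {
      warning("dropping constant covariate '", v, "'", call. = FALSE)
      dropped <- c(dropped, v)
      next
    }
    dat[[v]] <- col
  }
  rhs <- setdiff(names(dat), "y")
  form <- stats::as.formula(paste("y ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
  X <- stats::model.matrix(form, dat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- stats::fitted(fit)
  boundary <- any(mu < 1e-8 | mu > 1 - 1e-8)
  diverged <- length(stats::coef(fit)) > 1 &&
    max(abs(stats::coef(fit)[-1])) > 10
  if (boundary && diverged) {
    stop("complete or quasi-complete separation detected; coefficients diverge",
         call. = FALSE)
  }
  sm <- summary(fit)
  out <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, "Estimate"]),
    std_error = unname(sm$coefficients[, "Std. Error"])
  )
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "converged") <- fit$converged
  attr(out, "iterations") <- fit$iter
  attr(out, "dropped") <- dropped
  out
}

#' Age- and sex-adjusted odds ratios for one exposure variable
#'
#' Fits one logistic model per exposure
#' (`died ~ exposure + age band + sex`, age band referenced to 2-5
#' months, sex to female) and exponentiates the exposure coefficients;
#' CIs are `exp(estimate +/- 1.96 SE)`.
#'
#' @inheritParams categorical_or
#' @return List of `or_estimate` objects with `kind = "adjusted"`, one
#'   per non-reference category.
#' @export
adjusted_or <- function(records, variable,
                        reference_category = table1_reference(variable)) {
  covars <- unique(c(variable, "age_band", "sex"))
  refs <- stats::setNames(list(reference_category), variable)
  fit <- fit_logistic(records, covars, references = refs)
  z <- stats::qnorm(0.975)
  rows <- fit[startsWith(fit$term, variable), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    est <- rows$estimate[i]
    se <- rows$std_error[i]
    structure(
      list(odds_ratio = exp(est),
           ci_low = exp(est - z * se),
           ci_high = exp(est + z * se),
           kind = "adjusted",
           exposure_label = sub(paste0("^", variable), "", rows$term[i]),
           reference_label = reference_category),
      class = "or_estimate"
    )
  })
}
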