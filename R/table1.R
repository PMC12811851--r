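#' Round half away from zero
#'
#' Decimal rounding as used in the formatted descriptive tables (R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Descriptive table of a cohort stratified by outcome
#'
#' For each descriptive variable: counts and percentages overall, among
#' in-hospital deaths, and among discharges, plus crude (cross-product /
#' Woolf) and age/sex-adjusted (logistic) odds ratios for each
#' non-reference category. Percentages and odds ratios are returned
#' unrounded; [write_table1_csv()] formats to 1 decimal. The first row
#' reports the overall case fatality rate.
#'
#' @param records Cohort tibble restricted to died/discharged outcomes
#'   with complete descriptive fields (the primary-cohort situation).
#' @param adjusted Also fit the per-variable age/sex-adjusted models
#'   (default `TRUE`).
#' @return Tibble with columns `variable`, `category`, `is_reference`,
#'   `n_all`, `pct_all`, `n_died`, `pct_died`, `n_discharged`,
#'   `pct_discharged`, `or`, `or_lo`, `or_hi`, `aor`, `aor_lo`, `aor_hi`.
#' @export
build_table1 <- function(records, adjusted = TRUE) {
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  if (!all(records$outcome %in% c("died", "discharged"))) {
    stop("descriptive table expects died/discharged outcomes only",
         call. = FALSE)
  }
  cats <- table1_categories(records)
  died <- cats$outcome == "died"
  n <- nrow(records)
  n_died <- sum(died)
  n_disc <- n - n_died

  rows <- list(tibble::tibble(
    variable = "overall", category = "all", is_reference = FALSE,
    n_all = n, pct_all = 100,
    n_died = n_died, pct_died = 100 * n_died / n,
    n_discharged = n_disc, pct_discharged = 100 * n_disc / n,
    or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
    aor = NA_real_, aor_lo = NA_real_, aor_hi = NA_real_
  ))

  for (v in table1_variables()) {
    x <- cats[[v]]
    ref <- table1_reference(v)
    levels_ <- unique(x[!is.na(x)])
    ordered_levels <- c(intersect(ref, levels_), setdiff(levels_, ref))
    crude <- tryCatch(categorical_or(records, v), error = function(e) NULL)
    adj <- if (adjusted) {
      tryCatch(adjusted_or(records, v), error = function(e) NULL)
    }
    lookup <- function(estimates, lv) {
      if (is.null(estimates)) return(NULL)
      hit <- Filter(function(e) e$exposure_label == lv, estimates)
      if (length(hit)) hit[[1]] else NULL
    }
    for (lv in ordered_levels) {
      sel <- !is.na(x) & x == lv
      co <- lookup(crude, lv)
      ao <- lookup(adj, lv)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, category = lv, is_reference = lv == ref,
        n_all = sum(sel), pct_all = 100 * sum(sel) / n,
        n_died = sum(sel & died), pct_died = 100 * sum(sel & died) / n_died,
        n_discharged = sum(sel & !died),
        pct_discharged = 100 * sum(sel & !died) / n_disc,
        or = if (is.null(co)) NA_real_ else co$odds_ratio,
        or_lo = if (is.null(co)) NA_real_ else co$ci_low,
        or_hi = if (is.null(co)) NA_real_ else co$ci_high,
        aor = if (is.null(ao)) NA_real_ else ao$odds_ratio,
        aor_lo = if (is.null(ao)) NA_real_ else ao$ci_low,
        aor_hi = if (is.null(ao)) NA_real_ else ao$ci_high
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a formatted descriptive table
#'
#' Formats [build_table1()] output to the published convention
#' (percentages and odds ratios rounded half away from zero to 1
#' decimal) and writes CSV.
#'
#' @param table1 Output of [build_table1()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table1_csv <- function(table1, path) {
  out <- table1
  for (col in c("pct_all", "pct_died", "pct_discharged",
                "or", "or_lo", "or_hi", "aor", "aor_lo", "aor_hi")) {
    out[[col]] <- round_half_up(out[[col]], 1)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Published outcome-stratified counts of the Kilifi validation cohort
#'
#' The outcome-stratified category counts published for the 2182-admission
#' primary cohort (152 deaths, 2030 discharges), as packaged data. Sign
#' variables carry only the sign-present row; the absent reference row is
#' the complement against the overall outcome totals.
#'
#' @return Tibble with columns `variable`, `category`, `is_reference`,
#'   `n_died`, `n_discharged`.
#' @export
published_table1_counts <- function() {
  path <- system.file("extdata", "table1_published_counts.csv",
                      package = "alriscore", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(raw)
}

#' Crude odds ratios recomputed from the published counts
#'
#' Rebuilds each variable's 2x2 tables from [published_table1_counts()]
#' (sign variables get their absent reference cells by complement against
#' the overall outcome totals) and recomputes the cross-product odds
#' ratio with Woolf confidence interval for every non-reference category.
#'
#' @return Tibble with columns `variable`, `category`, `odds_ratio`,
#'   `ci_low`, `ci_high`.
#' @export
published_crude_ors <- function() {
  counts <- published_table1_counts()
  overall <- counts[counts$variable == "overall", ]
  rows <- list()
  for (v in setdiff(unique(counts$variable), "overall")) {
    sub <- counts[counts$variable == v, ]
    if (any(sub$is_reference == 1)) {
      ref <- sub[sub$is_reference == 1, ]
      c_ref <- ref$n_died
      d_ref <- ref$n_discharged
    } else {
      # sign variable: reference = absent, by complement
      c_ref <- overall$n_died - sum(sub$n_died)
      d_ref <- overall$n_discharged - sum(sub$n_discharged)
    }
    for (i in which(sub$is_reference == 0)) {
      est <- crude_or(a = sub$n_died[i], b = sub$n_discharged[i],
                      c = c_ref, d = d_ref,
                      exposure_label = sub$category[i])
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, category = sub$category[i],
        odds_ratio = est$odds_ratio, ci_low = est$ci_low,
        ci_high = est$ci_high
      )
    }
  }
  do.call(rbind, rows)
}
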