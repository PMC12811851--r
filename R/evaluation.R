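## Discrimination of score totals against in-hospital mortality.
##
## The AUROC is the Mann-Whitney estimator: the proportion of
## (death, discharge) pairs in which the death has the higher score, ties
## counted 1/2. Variances, covariances and paired tests use the
## nonparametric structural-component (placement-value) decomposition of
## DeLong, DeLong & Clarke-Pearson (1988); placements are computed with
## midranks in O(n log n).

check_binary_outcomes <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must be aligned", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(outcomes)) {
    stop("scores and outcomes must be complete", call. = FALSE)
  }
  outcomes <- as.integer(outcomes)
  if (!all(outcomes %in% c(0L, 1L))) {
    stop("outcomes must be binary (0 = discharged, 1 = died)", call. = FALSE)
  }
  if (sum(outcomes) == 0 || sum(outcomes) == length(outcomes)) {
    stop("degenerate outcomes: both deaths and discharges are required",
         call. = FALSE)
  }
  outcomes
}

## Placement values: V10[i] = P-hat(score of death i > score of a random
## discharge) with ties 1/2, and symmetrically V01 for discharges.
delong_placements <- function(scores, outcomes) {
  pos <- scores[outcomes == 1L]
  neg <- scores[outcomes == 0L]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auroc = mean(v10), m = m, n = n)
}

#' Empirical AUROC of a score for a binary outcome
#'
#' Mann-Whitney estimator with midrank tie handling: the mean over all
#' (death, discharge) pairs of 1 if the death scores higher, 1/2 on a
#' tie, 0 otherwise.
#'
#' @param scores Numeric score totals.
#' @param outcomes Binary outcomes aligned with `scores` (1 = died,
#'   0 = discharged; logicals accepted).
#' @return The AUROC, a fraction in `[0, 1]`.
#' @export
empirical_auroc <- function(scores, outcomes) {
  outcomes <- check_binary_outcomes(scores, outcomes)
  delong_placements(scores, outcomes)$auroc
}

#' AUROC with DeLong variance and confidence interval
#'
#' Estimates the AUROC and its sampling variance from the DeLong
#' structural components (the sample variances of the per-death and
#' per-discharge placement values), then forms a normal-theory interval.
#' The default interval is Wald on the AUROC scale truncated to
#' `[0, 1]`; `ci_method = "logit"` transforms instead.
#'
#' @inheritParams empirical_auroc
#' @param score_id Label carried into the result.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"wald"` (default) or `"logit"`.
#' @return A `roc_analysis` list: `score_id`, `auroc`, `delong_variance`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`, `band` (see
#'   [discrimination_band()]).
#' @export
delong_ci <- function(scores, outcomes, score_id = "score", level = 0.95,
                      ci_method = c("wald", "logit")) {
  ci_method <- match.arg(ci_method)
  outcomes <- check_binary_outcomes(scores, outcomes)
  pl <- delong_placements(scores, outcomes)
  if (pl$m < 2 || pl$n < 2) {
    stop("DeLong variance requires at least 2 deaths and 2 discharges",
         call. = FALSE)
  }
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci_method == "wald") {
    lo <- max(0, pl$auroc - z * sqrt(v))
    hi <- min(1, pl$auroc + z * sqrt(v))
  } else {
    if (pl$auroc <= 0 || pl$auroc >= 1 || v == 0) {
      lo <- hi <- pl$auroc
    } else {
      se_logit <- sqrt(v) / (pl$auroc * (1 - pl$auroc))
      lg <- stats::qlogis(pl$auroc)
      lo <- stats::plogis(lg - z * se_logit)
      hi <- stats::plogis(lg + z * se_logit)
    }
  }
  structure(
    list(score_id = score_id, auroc = pl$auroc, delong_variance = v,
         ci_low = lo, ci_high = hi, n_pos = pl$m, n_neg = pl$n,
         band = discrimination_band(pl$auroc)),
    class = "roc_analysis"
  )
}

#' Paired DeLong test between two correlated AUROCs
#'
#' Both scores are measured on the same subjects; the test statistic is
#' `z = (A_a - A_b) / sqrt(var_a + var_b - 2 cov_ab)` with variance and
#' covariance from the paired placement values, referred to the standard
#' normal (two-sided).
#'
#' @param scores_a,scores_b Score totals for the same subjects.
#' @param outcomes Shared binary outcomes.
#' @param significance_level Flagging threshold for `significant` in the
#'   result (default 0.01).
#' @return A `paired_comparison` list: `auroc_a`, `auroc_b`,
#'   `z_statistic`, `p_value`, `significant`.
#' @export
delong_paired_test <- function(scores_a, scores_b, outcomes,
                               significance_level = 0.01) {
  outcomes <- check_binary_outcomes(scores_a, outcomes)
  check_binary_outcomes(scores_b, outcomes)
  pa <- delong_placements(scores_a, outcomes)
  pb <- delong_placements(scores_b, outcomes)
  if (pa$m < 2 || pa$n < 2) {
    stop("paired DeLong test requires at least 2 deaths and 2 discharges",
         call. = FALSE)
  }
  var_a <- stats::var(pa$v10) / pa$m + stats::var(pa$v01) / pa$n
  var_b <- stats::var(pb$v10) / pb$m + stats::var(pb$v01) / pb$n
  cov_ab <- stats::cov(pa$v10, pb$v10) / pa$m + stats::cov(pa$v01, pb$v01) / pa$n
  var_diff <- var_a + var_b - 2 * cov_ab
  delta <- pa$auroc - pb$auroc
  if (var_diff <= .Machine$double.eps^0.5) {
    if (abs(delta) <= .Machine$double.eps^0.5) {
      z <- 0
      p <- 1
    } else {
      stop("degenerate paired variance with unequal AUROCs", call. = FALSE)
    }
  } else {
    z <- delta / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auroc_a = pa$auroc, auroc_b = pb$auroc, z_statistic = z, p_value = p,
         significant = p < significance_level),
    class = "paired_comparison"
  )
}

#' Operating characteristics at every observed threshold
#'
#' For each distinct observed score value `c`, classifies `score >= c` as
#' high risk and reports sensitivity (`P(score >= c | died)`),
#' specificity (`P(score < c | discharged)`), the Youden J index
#' (`sensitivity + specificity - 1`), the proportion of the cohort
#' classed high risk, and the observed case fatality rate among the
#' high-risk group (`NA` when no one is high risk).
#'
#' @inheritParams empirical_auroc
#' @return Tibble with one row per distinct score value, ascending, and
#'   columns `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   `proportion_high_risk`, `observed_cfr_high_risk`.
#' @export
threshold_table <- function(scores, outcomes) {
  outcomes <- check_binary_outcomes(scores, outcomes)
  cutoffs <- sort(unique(scores))
  n <- length(scores)
  n_pos <- sum(outcomes)
  n_neg <- n - n_pos
  rows <- lapply(cutoffs, function(cc) {
    high <- scores >= cc
    tp <- sum(high & outcomes == 1L)
    fp <- sum(high & outcomes == 0L)
    sens <- tp / n_pos
    spec <- (n_neg - fp) / n_neg
    tibble::tibble(
      cutoff = cc,
      sensitivity = sens,
      specificity = spec,
      youden_j = sens + spec - 1,
      proportion_high_risk = (tp + fp) / n,
      observed_cfr_high_risk = if (tp + fp > 0) tp / (tp + fp) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Youden-optimal threshold row
#'
#' The row of a [threshold_table()] maximizing the Youden J index; ties
#' are broken toward the smallest cutoff.
#'
#' @param table A threshold table.
#' @return A one-row tibble.
#' @export
optimal_cutoff <- function(table) {
  if (nrow(table) == 0) stop("empty threshold table", call. = FALSE)
  table[which.max(table$youden_j), , drop = FALSE]
}

#' Stratified AUROC analysis
#'
#' Runs [delong_ci()] independently within each stratum. Strata lacking
#' both outcome classes (or with fewer than 2 of either class) are
#' reported as skipped with a reason rather than raising.
#'
#' @inheritParams empirical_auroc
#' @param strata Stratum labels aligned with `scores`.
#' @param score_id Label carried into each result.
#' @return Tibble with columns `stratum`, `n`, `skipped`, `reason`,
#'   `auroc`, `ci_low`, `ci_high`, `band`.
#' @export
stratified_auroc <- function(scores, outcomes, strata, score_id = "score") {
  outcomes <- as.integer(outcomes)
  levels_ <- unique(strata)
  rows <- lapply(levels_, function(s) {
    idx <- strata == s
    o <- outcomes[idx]
    base <- tibble::tibble(stratum = s, n = sum(idx), skipped = FALSE,
                           reason = NA_character_, auroc = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_,
                           band = NA_character_)
    if (sum(o == 1L) < 2 || sum(o == 0L) < 2) {
      base$skipped <- TRUE
      base$reason <- "fewer than 2 records in one outcome class"
      return(base)
    }
    ra <- delong_ci(scores[idx], o, score_id = score_id)
    base$auroc <- ra$auroc
    base$ci_low <- ra$ci_low
    base$ci_high <- ra$ci_high
    base$band <- ra$band
    base
  })
  do.call(rbind, rows)
}

#' Qualitative discrimination band of an AUROC
#'
#' Hosmer-Lemeshow style interpretation bands: below 0.50 no
#' discrimination, 0.50-0.69 poor, 0.70-0.79 acceptable, 0.80-0.89 good,
#' 0.90 and above excellent. Applied to the unrounded value.
#'
#' @param auroc AUROC value(s) in `[0, 1]`.
#' @return Character vector over `none`, `poor`, `acceptable`, `good`,
#'   `excellent`.
#' @export
discrimination_band <- function(auroc) {
  if (any(auroc < 0 | auroc > 1, na.rm = TRUE)) {
    stop("auroc must lie in [0, 1]", call. = FALSE)
  }
  ifelse(auroc < 0.5, "none",
         ifelse(auroc < 0.7, "poor",
                ifelse(auroc < 0.8, "acceptable",
                       ifelse(auroc < 0.9, "good", "excellent"))))
}

#' Pairwise DeLong comparison matrix
#'
#' All pairwise two-sided DeLong tests among the score columns of a score
#' matrix, against a shared outcome vector.
#'
#' @param score_matrix Tibble from [compute_score_matrix()] (or any tibble
#'   whose non-`admission_id` columns are score totals).
#' @param outcomes Binary outcomes aligned with the rows.
#' @return Square numeric matrix of p-values (diagonal 1) with score ids
#'   as dimnames.
#' @export
pairwise_auroc_pvalues <- function(score_matrix, outcomes) {
  ids <- setdiff(names(score_matrix), "admission_id")
  p <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        cmp <- delong_paired_test(score_matrix[[ids[i]]],
                                  score_matrix[[ids[j]]], outcomes)
        p[i, j] <- p[j, i] <- cmp$p_value
      }
    }
  }
  p
}
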