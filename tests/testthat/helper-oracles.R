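# Independent brute-force oracles, O(n^2), used only to check the
# rank-based implementations on small inputs.

bf_auroc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Placement values straight from the definition of the DeLong structural
# components: per-death and per-discharge empirical placement.
bf_placements <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(vapply(neg, function(y) psi(x, y), 0)), 0)
  v01 <- vapply(neg, function(y) mean(vapply(pos, function(x) psi(x, y), 0)), 0)
  list(v10 = v10, v01 = v01, m = length(pos), n = length(neg))
}

bf_delong_var <- function(scores, outcomes) {
  pl <- bf_placements(scores, outcomes)
  stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
}

bf_delong_cov <- function(scores_a, scores_b, outcomes) {
  pa <- bf_placements(scores_a, outcomes)
  pb <- bf_placements(scores_b, outcomes)
  stats::cov(pa$v10, pb$v10) / pa$m + stats::cov(pa$v01, pb$v01) / pa$n
}

# Exhaustive recount of the operating characteristics at one cutoff.
bf_threshold_row <- function(scores, outcomes, cutoff) {
  high <- scores >= cutoff
  sens <- sum(high & outcomes == 1) / sum(outcomes == 1)
  spec <- sum(!high & outcomes == 0) / sum(outcomes == 0)
  c(sensitivity = sens, specificity = spec, youden_j = sens + spec - 1,
    proportion_high_risk = mean(high),
    observed_cfr_high_risk = if (any(high)) sum(high & outcomes == 1) / sum(high) else NA_real_)
}

# Newton-Raphson logistic MLE on a raw design matrix, independent of glm.
bf_logistic_newton <- function(X, y, iter = 60) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- drop(t(X) %*% (y - mu))
    hess <- t(X) %*% (X * w)
    beta <- beta + solve(hess, grad)
  }
  beta
}
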