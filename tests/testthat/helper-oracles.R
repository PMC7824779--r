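# Independent oracles used to cross-check the package's estimators.
# These deliberately avoid the code paths they verify: the logistic oracle is
# an exhaustive grid search over the log-likelihood surface, the AUC oracle
# counts case-control pairs directly, and the ROC oracle enumerates
# thresholds by hand.

# Binomial log-likelihood of logit P(y=1) = a + b*d at one (a, b).
loglik_logistic <- function(a, b, y, d) {
  eta <- a + b * d
  sum(y * eta - log1p(exp(eta)))
}

# Exhaustive two-stage grid search for the ML slope: coarse 0.05 grid over
# [-8, 8]^2, then a 0.0005 grid around the coarse optimum. Resolution is
# well below the 1e-3 comparison tolerance. Only meaningful when the MLE is
# interior (no separation).
oracle_logistic_beta <- function(y, d) {
  scan_grid <- function(a_grid, b_grid) {
    best <- c(-Inf, NA, NA)
    for (b in b_grid) {
      eta <- outer(a_grid, b * d, `+`)
      ll <- as.vector((eta %*% y) - rowSums(log1p(exp(eta))))
      i <- which.max(ll)
      if (ll[i] > best[1]) best <- c(ll[i], a_grid[i], b)
    }
    best
  }
  coarse <- scan_grid(seq(-8, 8, by = 0.05), seq(-8, 8, by = 0.05))
  fine <- scan_grid(seq(coarse[2] - 0.06, coarse[2] + 0.06, by = 5e-4),
                    seq(coarse[3] - 0.06, coarse[3] + 0.06, by = 5e-4))
  c(alpha = fine[2], beta = fine[3])
}

# Mann-Whitney pair-counting AUC: proportion of case-control pairs where the
# case scores higher, ties counting one half. O(n1 * n0).
oracle_auc_paircount <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Enumerate ROC operating points by scanning every candidate threshold
# (each distinct score, plus sentinels) with the >= classification rule.
oracle_roc_points <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(x >= t), numeric(1)),
    specificity = vapply(th, function(t) mean(y < t), numeric(1))
  )
}

# Random small case-control instance with non-degenerate dosages, for
# oracle-equivalence sweeps. Rejects separated instances (oracle grid search
# is only valid at interior MLEs).
random_toy_instance <- function(n_max = 12) {
  repeat {
    n <- sample(6:n_max, 1)
    y <- c(rep(1L, ceiling(n / 2)), rep(0L, floor(n / 2)))
    d <- sample(0:2, n, replace = TRUE)
    if (length(unique(d)) < 2) next
    fit <- suppressWarnings(
      stats::glm(y ~ d, family = stats::binomial())
    )
    beta <- stats::coef(fit)[["d"]]
    se <- summary(fit)$coefficients["d", "Std. Error"]
    if (abs(beta) < 5 && se < 10) {
      return(list(y = y, d = d))
    }
  }
}

# A tiny cohort built directly from vectors, for algebraic unit tests.
toy_cohort <- function(dosage, phenotype, ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(dosage)))
  cohort(ids, phenotype, dosage)
}
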