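# Empirical ROC analysis of a risk score: curve, trapezoid AUC, DeLong CI,
# Youden best discriminating point. The classification rule is fixed to
# risk-score semantics: predict "case" when score >= threshold, so a higher
# score always means higher predicted risk (no automatic direction flip).

#' Empirical ROC curve of a risk score
#'
#' One operating point per distinct score value (threshold = that value,
#' predict case when score >= threshold) plus `+Inf` and `-Inf` sentinels, so
#' the curve runs from (sensitivity 0, specificity 1) to (sensitivity 1,
#' specificity 0). The AUC is the trapezoidal area under the empirical
#' curve, which equals the Mann-Whitney two-sample statistic: the proportion
#' of case-control pairs where the case scores higher, ties counting 1/2.
#'
#' @param scores Numeric vector of risk scores (finite).
#' @param labels 0/1 vector; 1 = case.
#' @param ci Confidence-interval method for the AUC: `"delong"` (default) or
#'   `"bootstrap"` (stratified percentile bootstrap).
#' @param level Confidence level.
#' @param boot_n Bootstrap resamples when `ci = "bootstrap"`.
#' @return A `roc_curve`: list with descending `thresholds`, aligned
#'   `sensitivity` and `specificity`, `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `ci_method`, and the Youden best point (`best_threshold`,
#'   `best_sensitivity`, `best_specificity`).
#' @examples
#' rc <- roc_curve(c(2, 3, 0, 1), c(1, 1, 0, 0))
#' rc$auc  # 1: separable
#' @export
roc_curve <- function(scores, labels, ci = c("delong", "bootstrap"),
                      level = 0.95, boot_n = 2000) {
  ci <- match.arg(ci)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  case_scores <- scores[labels == 1L]
  ctrl_scores <- scores[labels == 0L]
  sens <- vapply(thresholds, function(t) mean(case_scores >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(ctrl_scores < t), numeric(1))

  a <- auc_trapezoid(sens, spec)
  ci_bounds <- switch(ci,
    delong = auc_ci_delong(scores, labels, level = level),
    bootstrap = auc_ci_bootstrap(scores, labels, level = level, boot_n = boot_n)
  )
  curve <- structure(list(thresholds = thresholds, sensitivity = sens,
                          specificity = spec, auc = a,
                          auc_ci_low = ci_bounds[[1]],
                          auc_ci_high = ci_bounds[[2]],
                          ci_method = ci),
                     class = "roc_curve")
  best <- best_point_youden(curve)
  curve$best_threshold <- best[["threshold"]]
  curve$best_sensitivity <- best[["sensitivity"]]
  curve$best_specificity <- best[["specificity"]]
  curve
}

# Trapezoid over the (1 - specificity, sensitivity) polyline.
auc_trapezoid <- function(sens, spec) {
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  x <- fpr[ord]; y <- sens[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal AUC; numerically identical to the Mann-Whitney estimator
#' `(1/(n1*n0)) * sum over case-control pairs of [case > control] + [==]/2`.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  case_scores <- scores[labels == 1L]
  ctrl_scores <- scores[labels == 0L]
  sens <- vapply(thresholds, function(t) mean(case_scores >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(ctrl_scores < t), numeric(1))
  auc_trapezoid(sens, spec)
}

# Midrank placement values: V10_i = P-hat(case i outranks a random control).
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rank(x, ties.method = "average")) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the empirical AUC from the placement values of
#' cases and controls, with a normal-approximation interval truncated to
#' `[0, 1]`. When every placement is identical (e.g. perfectly separated
#' data) the variance is zero and the interval collapses to the point
#' estimate, with a warning.
#'
#' @inheritParams roc_curve
#' @return Named numeric `c(low, high)`.
#' @export
auc_ci_delong <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2 || n0 < 2) stop("DeLong CI needs at least 2 cases and 2 controls")
  pl <- delong_placements(scores, labels)
  a <- mean(pl$v10)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  if (v <= 0) {
    warning("degenerate DeLong variance; interval collapses to the point AUC")
    return(c(low = a, high = a))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = max(0, a - z * sqrt(v)), high = min(1, a + z * sqrt(v)))
}

# Stratified percentile bootstrap CI (resampling cases and controls
# separately), available as an alternative to DeLong.
auc_ci_bootstrap <- function(scores, labels, level = 0.95, boot_n = 2000) {
  labels <- as.integer(labels)
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  stats_ <- replicate(boot_n, {
    i1 <- sample(idx1, replace = TRUE)
    i0 <- sample(idx0, replace = TRUE)
    auc(c(scores[i1], scores[i0]),
        c(rep(1L, length(i1)), rep(0L, length(i0))))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_, c(alpha, 1 - alpha), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Best discriminating point of an ROC curve (Youden)
#'
#' The operating point maximising the Youden index
#' `sensitivity + specificity - 1`. Ties are broken deterministically toward
#' higher sensitivity, then toward the lower threshold.
#'
#' @param curve A `roc_curve`.
#' @return Named numeric `c(threshold, sensitivity, specificity)`.
#' @export
best_point_youden <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[curve$sensitivity[best] == max(curve$sensitivity[best])]
  best <- best[which.min(curve$thresholds[best])]
  c(threshold = curve$thresholds[best],
    sensitivity = curve$sensitivity[best],
    specificity = curve$specificity[best])
}

#' @export
print.roc_curve <- function(x, digits = 3, ...) {
  cat("Empirical ROC over", length(x$thresholds) - 2, "distinct score values\n")
  cat(sprintf("AUC %.*f (%d%% CI %s: %.*f, %.*f)\n", digits, x$auc,
              95L, x$ci_method, digits, x$auc_ci_low, digits, x$auc_ci_high))
  cat(sprintf("Best point (Youden): threshold %.*f, sensitivity %.*f, specificity %.*f\n",
              digits, x$best_threshold, digits, x$best_sensitivity,
              digits, x$best_specificity))
  invisible(x)
}

#' Write ROC outputs as TSV
#'
#' Writes the operating points (`<prefix>_points.tsv`: threshold,
#' sensitivity, specificity) and a one-row summary
#' (`<prefix>_summary.tsv`: auc, ci bounds, best point).
#'
#' @param curve A `roc_curve`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_roc_tables <- function(curve, prefix) {
  pts <- data.frame(threshold = curve$thresholds,
                    sensitivity = curve$sensitivity,
                    specificity = curve$specificity)
  p1 <- paste0(prefix, "_points.tsv")
  utils::write.table(pts, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- data.frame(auc = curve$auc, ci_low = curve$auc_ci_low,
                   ci_high = curve$auc_ci_high, ci_method = curve$ci_method,
                   best_threshold = curve$best_threshold,
                   best_sensitivity = curve$best_sensitivity,
                   best_specificity = curve$best_specificity)
  p2 <- paste0(prefix, "_summary.tsv")
  utils::write.table(sm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(points = p1, summary = p2))
}
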