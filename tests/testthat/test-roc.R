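test_that("separable scores give a perfect curve and a degenerate interval", {
  scores <- c(2, 3, 0, 1)
  labels <- c(1, 1, 0, 0)
  expect_warning(rc <- roc_curve(scores, labels), "degenerate")
  expect_equal(rc$auc, 1)
  # a threshold achieving sensitivity 1 and specificity 1 exists
  expect_true(any(rc$sensitivity == 1 & rc$specificity == 1))
  expect_equal(rc$best_sensitivity, 1)
  expect_equal(rc$best_specificity, 1)
  expect_equal(rc$auc_ci_high, 1)
  expect_equal(rc$auc_ci_low, rc$auc)
})

test_that("curve endpoints and monotonicity hold, ties give the diagonal", {
  set.seed(14)
  scores <- round(rnorm(30), 1)
  labels <- rep(c(1, 0), 15)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$sensitivity[1], 0)
  expect_equal(rc$specificity[1], 1)
  expect_equal(rc$sensitivity[length(rc$sensitivity)], 1)
  expect_equal(rc$specificity[length(rc$specificity)], 0)
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(diff(rc$specificity) <= 0))

  tied <- rep(1.5, 10)
  rc_t <- suppressWarnings(roc_curve(tied, rep(c(1, 0), 5)))
  expect_equal(rc_t$auc, 0.5)
  expect_equal(max(rc_t$sensitivity + rc_t$specificity - 1), 0)
})

test_that("operating points match exhaustive threshold enumeration", {
  scores <- c(0.3, 0.7, 0.7, 0.1, 0.5, 0.9)  # one tie across groups
  labels <- c(1, 1, 0, 0, 0, 1)
  rc <- roc_curve(scores, labels)
  oracle <- oracle_roc_points(scores, labels)
  expect_equal(rc$thresholds, oracle$threshold)
  expect_equal(rc$sensitivity, oracle$sensitivity)
  expect_equal(rc$specificity, oracle$specificity)
})

test_that("trapezoid AUC equals Mann-Whitney pair counting", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:100, 1); n0 <- sample(2:100, 1)
    scores <- c(rnorm(n1, 0.3), rnorm(n0))
    if (i %% 2 == 0) scores <- round(scores, 1)  # force ties half the time
    labels <- rep(c(1L, 0L), c(n1, n0))
    expect_equal(auc(scores, labels), oracle_auc_paircount(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is complementary under score negation and invariant to monotone maps", {
  set.seed(17)
  scores <- round(rnorm(80), 1)
  labels <- rep(c(1, 0), 40)
  a <- auc(scores, labels)
  expect_equal(a + auc(-scores, labels), 1, tolerance = 1e-12)
  expect_identical(auc(exp(scores), labels), a)
  expect_identical(auc(3 * scores + 7, labels), a)
})

test_that("random label permutation gives a null AUC of one half", {
  set.seed(23)
  scores <- rnorm(40)
  aucs <- replicate(2000, auc(scores, sample(rep(c(1, 0), 20))))
  expect_equal(mean(aucs), 0.5, tolerance = 0.01)
})

test_that("DeLong interval brackets the AUC and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:10) {
    n1 <- sample(10:60, 1); n0 <- sample(10:60, 1)
    scores <- c(rnorm(n1, 0.8), rnorm(n0))
    if (i > 5) scores <- round(scores, 1)
    labels <- rep(c(1L, 0L), c(n1, n0))
    ours <- auc_ci_delong(scores, labels)
    a <- auc(scores, labels)
    expect_lte(ours[["low"]], a)
    expect_gte(ours[["high"]], a)

    ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    expect_equal(a, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(unname(ours[["low"]]), max(0, ref_ci[1]), tolerance = 1e-10)
    expect_equal(unname(ours[["high"]]), min(1, ref_ci[3]), tolerance = 1e-10)
  }
})

test_that("bootstrap interval is a usable alternative", {
  set.seed(53)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c(1L, 0L), each = 40)
  rc <- roc_curve(scores, labels, ci = "bootstrap", boot_n = 500)
  expect_lte(rc$auc_ci_low, rc$auc)
  expect_gte(rc$auc_ci_high, rc$auc)
})

test_that("the Youden point matches a brute-force scan and its tie rules", {
  scores <- c(0.9, 0.8, 0.8, 0.6, 0.4, 0.4, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0)
  rc <- suppressWarnings(roc_curve(scores, labels))
  # brute force over every threshold
  cand <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  j <- vapply(cand, function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  }, numeric(1))
  expect_equal(rc$best_sensitivity + rc$best_specificity - 1, max(j),
               tolerance = 1e-12)

  # tie between two thresholds with equal J: higher sensitivity wins
  s2 <- c(4, 3, 2, 1)
  l2 <- c(1, 0, 1, 0)
  rc2 <- roc_curve(s2, l2)
  js <- rc2$sensitivity + rc2$specificity - 1
  ties <- which(js == max(js))
  expect_equal(rc2$best_sensitivity, max(rc2$sensitivity[ties]))
})

test_that("single-class labels are rejected", {
  expect_error(roc_curve(c(1, 2, 3), c(1, 1, 1)), "at least one")
  expect_error(auc(c(1, 2), c(0, 0)), "at least one")
})
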