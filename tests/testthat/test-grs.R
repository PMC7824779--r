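panel12 <- apply_ld_exclusion(build_default_panel())

test_that("missingness correction algebra is exact", {
  # 3 samples over 3 weighted variants; M_total deliberately larger (12)
  dos <- rbind(c(2, 1, 0),    # fully genotyped
               c(2, NA, NA),  # one of three genotyped
               c(NA, 1, 2))
  colnames(dos) <- c("a", "b", "c")
  chrt <- toy_cohort(dos, phenotype = c(1, 0, 1))
  w <- c(a = 0.5, b = 1, c = 0.25)

  ss <- compute_grs(chrt, w, M_total = 12)
  expect_identical(ss$scores$corrected_score,
                   ifelse(ss$scores$m_genotyped == 12, ss$scores$raw_score,
                          ss$scores$raw_score * 12 / ss$scores$m_genotyped))

  # single genotyped variant, w = 0.5, d = 2: raw 1, corrected 12
  expect_equal(ss$scores$raw_score[2], 1.0)
  expect_equal(ss$scores$corrected_score[2], 12.0)
  expect_equal(ss$scores$m_genotyped, c(3L, 1L, 2L))

  # fully genotyped samples are bit-identical under the correction
  full <- compute_grs(chrt, w, M_total = 3)
  expect_identical(full$scores$corrected_score[1], full$scores$raw_score[1])
})

test_that("unit-weight corrected scores of fully genotyped samples are allele counts", {
  chrt <- simulate_frequency_matched(
    simulation_config(40, 40, "frequency_matched",
                      eaf_cases = setNames(rep(0.4, 12), panel12$variant_id),
                      eaf_controls = setNames(rep(0.4, 12), panel12$variant_id),
                      seed = 3))
  ss <- compute_grs(chrt, build_weight_scheme(panel12, "unit"))
  expect_true(all(ss$scores$corrected_score == round(ss$scores$corrected_score)))
  expect_true(all(ss$scores$corrected_score >= 0 &
                  ss$scores$corrected_score <= 24))
  expect_identical(ss$scores$corrected_score,
                   unname(rowSums(chrt$dosage[, panel12$variant_id])))
})

test_that("samples with no genotyped scored variant are excluded, not scored", {
  dos <- rbind(c(1, 2), c(NA, NA), c(0, 1))
  colnames(dos) <- c("a", "b")
  chrt <- toy_cohort(dos, phenotype = c(1, 0, 0))
  expect_warning(ss <- compute_grs(chrt, c(a = 1, b = 1)), "excluded")
  expect_equal(nrow(ss$scores), 2)
  expect_equal(ss$excluded, "s02")
})

test_that("a zero-weight variant changes scores only through m", {
  dos <- rbind(c(1, 2, NA), c(2, NA, 1))
  colnames(dos) <- c("a", "b", "z")
  chrt <- toy_cohort(dos, phenotype = c(1, 0))
  base <- compute_grs(chrt, c(a = 0.5, b = 0.25), M_total = 12)
  with_z <- compute_grs(chrt, c(a = 0.5, b = 0.25, z = 0), M_total = 12)
  expect_equal(with_z$scores$raw_score, base$scores$raw_score)
  expect_equal(base$scores$m_genotyped, c(2L, 1L))
  # sample 1: z missing, m unchanged; sample 2: z genotyped, m 1 -> 2
  expect_equal(with_z$scores$m_genotyped, c(2L, 2L))
  expect_equal(with_z$scores$corrected_score[1], base$scores$corrected_score[1])
  expect_equal(with_z$scores$corrected_score[2],
               base$scores$raw_score[2] * 12 / 2)
})

test_that("GRS association matches the grid-search oracle and null case", {
  # identical score multisets in both groups: OR of 1
  dos <- cbind(v1 = c(0, 1, 2, 2, 0, 1, 2, 2), v2 = c(1, 1, 0, 2, 1, 1, 0, 2))
  chrt <- toy_cohort(dos, phenotype = c(1, 1, 1, 1, 0, 0, 0, 0))
  ss <- compute_grs(chrt, c(v1 = 0.7, v2 = 0.3))
  res <- grs_association(ss, chrt)
  expect_equal(res$or_, 1, tolerance = 1e-6)

  # 8-sample toy against the enumerated log-likelihood
  set.seed(9)
  dos2 <- cbind(v1 = sample(0:2, 8, TRUE), v2 = sample(0:2, 8, TRUE))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  chrt2 <- toy_cohort(dos2, phenotype = y)
  ss2 <- compute_grs(chrt2, c(v1 = 0.4, v2 = 0.6))
  res2 <- grs_association(ss2, chrt2)
  if (res2$status == "ok") {
    oracle <- oracle_logistic_beta(y, ss2$scores$corrected_score)
    expect_lt(abs(res2$beta - oracle[["beta"]]), 1e-3)
  }
})

test_that("rescaling weights rescales the slope but not the inference", {
  chrt <- simulate_replik_template(seed = 12)
  w <- build_weight_scheme(panel12, "published_mixed", replik_study_betas())
  res1 <- grs_association(compute_grs(chrt, w), chrt)

  w2 <- w
  w2$weights <- w$weights * 3
  res2 <- grs_association(compute_grs(chrt, w2), chrt)

  expect_equal(res2$beta, res1$beta / 3, tolerance = 1e-8)
  expect_equal(res2$beta / res2$se, res1$beta / res1$se, tolerance = 1e-8)
  expect_equal(res2$p, res1$p, tolerance = 1e-8)
})

test_that("the sensitivity analysis reports all three weighting schemes", {
  chrt <- simulate_replik_template(seed = 20)
  assoc <- run_panel_association(chrt, panel12)
  betas <- setNames(assoc$beta, assoc$variant_id)
  out <- run_grs_sensitivity(chrt, panel12, betas)

  expect_equal(out$table$scheme, c("published_mixed", "study", "unit"))
  expect_equal(nrow(out$table), 3)

  # study-scheme weights are the per-variant estimates, passed through
  w_study <- build_weight_scheme(panel12, "study", betas)
  expect_equal(w_study$weights[assoc$variant_id],
               setNames(assoc$beta, assoc$variant_id))

  # unit scheme: if cases carry strictly more risk alleles, OR > 1
  dos <- cbind(v1 = c(2, 2, 2, 0, 0, 1), v2 = c(2, 1, 2, 0, 1, 0))
  chrt2 <- toy_cohort(dos, phenotype = c(1, 1, 1, 0, 0, 0))
  pan2 <- data.frame(variant_id = c("v1", "v2"), locus = c("g1", "g2"),
                     chrom_pos = NA, effect_allele = "A", other_allele = "G",
                     variant_class = "SNP", published_or = NA,
                     ld_excluded = FALSE, stringsAsFactors = FALSE)
  a2 <- run_panel_association(chrt2, pan2)
  out2 <- run_grs_sensitivity(chrt2, pan2, setNames(a2$beta, a2$variant_id))
  expect_gt(out2$table$or_[out2$table$scheme == "unit"], 1)
})

test_that("known GRS slope is recovered under case-control sampling", {
  # liability model whose slope on the (fully genotyped) corrected-score
  # scale is 0.4; a moderate replicate count keeps this test fast, the
  # full calibration lives in the acceptance suite
  w <- build_weight_scheme(panel12, "published_mixed", replik_study_betas())
  eafs <- replik_template_config(1)$eaf_controls
  slope <- 0.4
  fits <- vapply(1:40, function(s) {
    cfg <- simulation_config(114, 106, "logistic_liability",
                             eaf_population = eafs,
                             true_betas = slope * w$weights,
                             intercept = -1.3, seed = 5000 + s)
    chrt <- simulate_logistic(cfg)
    res <- grs_association(compute_grs(chrt, w), chrt)
    res$beta
  }, numeric(1))
  expect_equal(mean(fits), slope, tolerance = 4 * sd(fits) / sqrt(length(fits)))
})
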