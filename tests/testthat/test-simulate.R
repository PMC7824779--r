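freq_config <- function(eaf_cases, eaf_controls = eaf_cases,
                        n_cases = 50, n_controls = 40, seed = 11) {
  simulation_config(n_cases, n_controls, "frequency_matched",
                    eaf_cases = eaf_cases, eaf_controls = eaf_controls,
                    seed = seed)
}

test_that("frequency-matched simulation is deterministic and respects EAF bounds", {
  cfg <- freq_config(c(v1 = 0.3, v2 = 0, v3 = 1))
  a <- simulate_frequency_matched(cfg)
  b <- simulate_frequency_matched(cfg)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$phenotype, b$phenotype)

  expect_true(all(a$dosage[, "v2"] == 0))  # EAF 0: monomorphic other allele
  expect_true(all(a$dosage[, "v3"] == 2))  # EAF 1: monomorphic effect allele
  expect_equal(sum(a$phenotype == 1L), 50)
  expect_equal(sum(a$phenotype == 0L), 40)
})

test_that("simulated dosages have the configured binomial mean", {
  cfg <- freq_config(c(rs1800896 = 0.59), c(rs1800896 = 0.49),
                     n_cases = 100000, n_controls = 100, seed = 21)
  chrt <- simulate_frequency_matched(cfg)
  mean_case_dosage <- mean(chrt$dosage[chrt$phenotype == 1L, "rs1800896"])
  expect_equal(mean_case_dosage, 2 * 0.59, tolerance = 0.01)
})

test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  # chi-square HWE statistic should reject at about its nominal rate
  set.seed(91)
  n <- 800
  p <- 0.3
  rejections <- replicate(200, {
    d <- rbinom(n, 2, p)
    obs <- tabulate(d + 1, 3)
    phat <- mean(d) / 2
    expd <- n * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
    x2 <- sum((obs - expd)^2 / expd)
    x2 > qchisq(0.95, df = 1)
  })
  obs_rej <- mean(rejections)

  cfg <- freq_config(c(v = p), n_cases = n, n_controls = 10, seed = 33)
  sim_rej <- mean(replicate(200, {
    cfg$seed <- sample.int(1e6, 1)
    chrt <- simulate_frequency_matched(cfg)
    d <- chrt$dosage[chrt$phenotype == 1L, "v"]
    obs <- tabulate(d + 1, 3)
    phat <- mean(d) / 2
    expd <- n * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
    sum((obs - expd)^2 / expd) > qchisq(0.95, df = 1)
  }))
  expect_lt(sim_rej, 0.12)        # not significant in >= 95%-ish of replicates
  expect_lt(abs(sim_rej - obs_rej), 0.1)
})

test_that("logistic-liability simulation recovers effect direction and the null", {
  cfg <- simulation_config(2000, 2000, "logistic_liability",
                           eaf_population = c(v = 0.5),
                           true_betas = c(v = 1), intercept = -0.5, seed = 5)
  chrt <- simulate_logistic(cfg)
  expect_gt(eaf(chrt, "v", "cases"), eaf(chrt, "v", "controls"))

  null_cfg <- simulation_config(20000, 20000, "logistic_liability",
                                eaf_population = c(v = 0.4),
                                true_betas = c(v = 0), intercept = 0, seed = 6)
  null_chrt <- simulate_logistic(null_cfg)
  expect_lt(abs(eaf(null_chrt, "v", "cases") -
                eaf(null_chrt, "v", "controls")), 0.02)
})

test_that("unreachable case quotas fail after the attempt cap", {
  cfg <- simulation_config(50, 5, "logistic_liability",
                           eaf_population = c(v = 0.5),
                           true_betas = c(v = 0), intercept = -40, seed = 7)
  expect_error(simulate_logistic(cfg, max_attempts = 5), "generation failure")
})

test_that("missingness injection hits per-group quotas exactly", {
  cfg <- freq_config(c(v1 = 0.5, v2 = 0.3), n_cases = 114, n_controls = 106,
                     seed = 13)
  chrt <- simulate_frequency_matched(cfg)
  counts <- data.frame(cases = c(75L, 114L), controls = c(46L, 106L),
                       row.names = c("v1", "v2"))
  out <- inject_missingness(chrt, counts, seed = 99)

  is_case <- out$phenotype == 1L
  expect_equal(sum(is.na(out$dosage[is_case, "v1"])), 114 - 75)
  expect_equal(sum(is.na(out$dosage[!is_case, "v1"])), 106 - 46)
  expect_equal(sum(is.na(out$dosage[, "v2"])), 0)

  # quotas equal to group sizes leave the cohort unchanged
  full <- data.frame(cases = c(114L, 114L), controls = c(106L, 106L),
                     row.names = c("v1", "v2"))
  expect_identical(inject_missingness(chrt, full, seed = 1)$dosage, chrt$dosage)

  # already-missing cells count toward the quota
  again <- inject_missingness(out, counts, seed = 123)
  expect_identical(again$dosage, out$dosage)

  # quotas above the group size are a configuration error
  too_big <- data.frame(cases = c(200L, 114L), controls = c(46L, 106L),
                        row.names = c("v1", "v2"))
  expect_error(inject_missingness(chrt, too_big, seed = 1), "configuration")

  # a pattern leaving samples with no genotyped variant is rejected
  single <- simulate_frequency_matched(freq_config(c(v = 0.5), n_cases = 10,
                                                   n_controls = 10, seed = 2))
  zero <- data.frame(cases = 0L, controls = 0L, row.names = "v")
  expect_error(inject_missingness(single, zero, seed = 1),
               "no genotyped variant")
})

test_that("the REPLIK template config carries the printed cohort structure", {
  cfg <- replik_template_config(seed = 1)
  expect_equal(cfg$n_cases, 114L)
  expect_equal(cfg$n_controls, 106L)
  expect_equal(unname(cfg$eaf_cases["rs1801133"]), 0.30)
  expect_equal(unname(cfg$eaf_controls["rs1801133"]), 0.24)
  expect_equal(unname(cfg$genotyped_counts["rs2234693", ]),
               c(110L, 106L))
  expect_equal(length(cfg$eaf_cases), 12)

  chrt <- simulate_replik_template(seed = 1)
  expect_identical(chrt$dosage, simulate_replik_template(seed = 1)$dosage)
  expect_false(identical(chrt$dosage, simulate_replik_template(seed = 2)$dosage))
})
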