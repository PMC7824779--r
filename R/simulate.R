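# Cohort container and Hardy-Weinberg case-control simulator.

#' Construct a case-control genotype cohort
#'
#' A cohort bundles a sample-by-variant effect-allele dosage matrix (entries
#' 0, 1, 2 or `NA` for missing) with a binary phenotype (1 = case).
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param phenotype Integer vector of 0/1 case status, same length.
#' @param dosage Numeric matrix, rows = samples, columns = variants (named).
#' @return A `cohort` object (list with `sample_ids`, `phenotype`, `dosage`).
#' @export
cohort <- function(sample_ids, phenotype, dosage) {
  sample_ids <- as.character(sample_ids)
  phenotype <- as.integer(phenotype)
  dosage <- as.matrix(dosage)
  if (length(sample_ids) != length(phenotype) ||
      nrow(dosage) != length(sample_ids)) {
    stop("sample_ids, phenotype and dosage rows must agree in length")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (!all(phenotype %in% c(0L, 1L))) stop("phenotype must be 0/1")
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  if (is.null(colnames(dosage))) stop("dosage columns must be named by variant_id")
  rownames(dosage) <- sample_ids
  structure(list(sample_ids = sample_ids, phenotype = phenotype,
                 dosage = dosage),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Case-control cohort:", sum(x$phenotype == 1L), "cases /",
      sum(x$phenotype == 0L), "controls,", ncol(x$dosage), "variants\n")
  miss <- colMeans(is.na(x$dosage))
  if (any(miss > 0)) {
    cat("Missingness:", sum(is.na(x$dosage)), "cells (",
        round(100 * mean(miss), 1), "% average per variant )\n")
  }
  invisible(x)
}

#' Simulation configuration
#'
#' @description
#' Describes a synthetic case-control cohort in one of two modes:
#'
#' * `"frequency_matched"` — cases and controls each receive genotypes drawn
#'   under Hardy-Weinberg equilibrium at group-specific effect-allele
#'   frequencies (`eaf_cases`, `eaf_controls`). This reproduces a target
#'   allele-frequency contrast directly, without a disease model.
#' * `"logistic_liability"` — genotypes are drawn at population frequencies
#'   (`eaf_population`) and case status follows a logistic disease model
#'   `P(case) = plogis(intercept + sum_j beta_j d_ij)` with known
#'   `true_betas`; samples are drawn until the configured numbers of cases
#'   and controls are reached (case-control sampling). Used for parameter
#'   recovery, where the truth is known.
#'
#' Variants are simulated independently (no linkage disequilibrium), matching
#' the analysis assumption of a pruned panel spanning distinct loci.
#'
#' @param n_cases,n_controls Positive integers.
#' @param mode `"frequency_matched"` or `"logistic_liability"`.
#' @param eaf_cases,eaf_controls Named frequency vectors in `[0,1]`
#'   (frequency-matched mode).
#' @param eaf_population Named frequency vector (liability mode).
#' @param true_betas Named log-odds effects (liability mode).
#' @param intercept Log-odds intercept of the liability model.
#' @param genotyped_counts Optional 2-column matrix or data frame (columns
#'   `cases`, `controls`, rows named by variant) giving how many individuals
#'   per group are genotyped for each variant; used by
#'   [inject_missingness()].
#' @param seed Integer seed governing all randomness of the generation.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_cases, n_controls,
                              mode = c("frequency_matched", "logistic_liability"),
                              eaf_cases = NULL, eaf_controls = NULL,
                              eaf_population = NULL, true_betas = NULL,
                              intercept = 0,
                              genotyped_counts = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_cases >= 1, n_controls >= 1)
  check_freq <- function(x, what) {
    if (is.null(x)) return(invisible(NULL))
    if (is.null(names(x)) || any(names(x) == "")) {
      stop(what, " must be a named vector (names = variant ids)")
    }
    if (any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]")
  }
  if (mode == "frequency_matched") {
    if (is.null(eaf_cases) || is.null(eaf_controls)) {
      stop("frequency_matched mode requires eaf_cases and eaf_controls")
    }
    check_freq(eaf_cases, "eaf_cases"); check_freq(eaf_controls, "eaf_controls")
    if (!identical(sort(names(eaf_cases)), sort(names(eaf_controls)))) {
      stop("eaf_cases and eaf_controls must cover the same variants")
    }
  } else {
    if (is.null(eaf_population) || is.null(true_betas)) {
      stop("logistic_liability mode requires eaf_population and true_betas")
    }
    check_freq(eaf_population, "eaf_population")
    if (!all(names(eaf_population) %in% names(true_betas))) {
      stop("true_betas must cover every variant in eaf_population")
    }
  }
  if (!is.null(genotyped_counts)) {
    genotyped_counts <- as.matrix(genotyped_counts[, c("cases", "controls")])
    if (any(genotyped_counts[, "cases"] > n_cases) ||
        any(genotyped_counts[, "controls"] > n_controls)) {
      stop("configuration error: genotyped_counts exceed group sizes")
    }
    if (any(genotyped_counts < 0)) stop("genotyped_counts must be non-negative")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 mode = mode,
                 eaf_cases = eaf_cases, eaf_controls = eaf_controls,
                 eaf_population = eaf_population, true_betas = true_betas,
                 intercept = intercept,
                 genotyped_counts = genotyped_counts,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run expr under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched, so repeated calls with one seed are bit-identical.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  expr
}

#' Simulate a frequency-matched case-control cohort
#'
#' Draws each dosage independently as Binomial(2, EAF of the sample's group)
#' — Hardy-Weinberg genotype proportions at the configured group-specific
#' effect-allele frequencies. Identical config and seed give a bit-identical
#' cohort.
#'
#' @param config A `sim_config` with `mode = "frequency_matched"`.
#' @return A [cohort()]; cases first (`case_1 ...`), then controls.
#' @export
simulate_frequency_matched <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "frequency_matched") {
    stop("config mode is not frequency_matched")
  }
  ids <- names(config$eaf_cases)
  n1 <- config$n_cases; n0 <- config$n_controls
  local_seed(config$seed, {
    dos <- matrix(NA_real_, nrow = n1 + n0, ncol = length(ids),
                  dimnames = list(NULL, ids))
    for (v in ids) {
      dos[seq_len(n1), v] <- stats::rbinom(n1, 2, config$eaf_cases[[v]])
      dos[n1 + seq_len(n0), v] <- stats::rbinom(n0, 2, config$eaf_controls[[v]])
    }
    cohort(sample_ids = c(sprintf("case_%03d", seq_len(n1)),
                          sprintf("ctrl_%03d", seq_len(n0))),
           phenotype = rep(c(1L, 0L), c(n1, n0)),
           dosage = dos)
  })
}

#' Simulate a cohort under a logistic disease model
#'
#' Genotypes are drawn under Hardy-Weinberg at population effect-allele
#' frequencies; each individual becomes a case with probability
#' `plogis(intercept + sum_j beta_j * d_ij)`. Individuals are accumulated by
#' rejection (case-control) sampling until the configured case and control
#' counts are reached; extras are discarded. Case-control sampling leaves the
#' slopes of the logistic model consistent (only the intercept is biased), so
#' fitted effects can be compared with `true_betas` directly.
#'
#' @param config A `sim_config` with `mode = "logistic_liability"`.
#' @param max_attempts Cap on total individuals drawn, as a multiple of
#'   `n_cases + n_controls`; generation fails beyond it (e.g. when the case
#'   probability is numerically zero).
#' @return A [cohort()]; cases first.
#' @export
simulate_logistic <- function(config, max_attempts = 100) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "logistic_liability") {
    stop("config mode is not logistic_liability")
  }
  ids <- names(config$eaf_population)
  beta <- config$true_betas[ids]
  n1 <- config$n_cases; n0 <- config$n_controls
  cap <- max_attempts * (n1 + n0)

  local_seed(config$seed, {
    kept_cases <- NULL; kept_ctrls <- NULL
    drawn <- 0L
    batch <- max(n1 + n0, 512L)
    while ((is.null(kept_cases) || nrow(kept_cases) < n1 ||
            nrow(kept_ctrls) < n0) && drawn < cap) {
      d <- vapply(ids, function(v) stats::rbinom(batch, 2, config$eaf_population[[v]]),
                  numeric(batch))
      if (batch == 1L) d <- matrix(d, nrow = 1, dimnames = list(NULL, ids))
      p <- stats::plogis(config$intercept + drop(d %*% beta))
      y <- stats::rbinom(batch, 1, p)
      drawn <- drawn + batch
      kept_cases <- rbind(kept_cases, d[y == 1L, , drop = FALSE])
      kept_ctrls <- rbind(kept_ctrls, d[y == 0L, , drop = FALSE])
    }
    if (nrow(kept_cases) < n1 || nrow(kept_ctrls) < n0) {
      stop("generation failure: could not reach ", n1, " cases / ", n0,
           " controls within ", cap, " draws; check intercept/true_betas")
    }
    dos <- rbind(kept_cases[seq_len(n1), , drop = FALSE],
                 kept_ctrls[seq_len(n0), , drop = FALSE])
    colnames(dos) <- ids
    cohort(sample_ids = c(sprintf("case_%03d", seq_len(n1)),
                          sprintf("ctrl_%03d", seq_len(n0))),
           phenotype = rep(c(1L, 0L), c(n1, n0)),
           dosage = dos)
  })
}

#' Inject per-variant, per-group missingness into a cohort
#'
#' For each variant and phenotype group, dosages are set to missing until
#' exactly `genotyped_count` genotyped individuals remain, with the missing
#' individuals chosen uniformly at random within the group (missing
#' completely at random given phenotype). Cells that are already missing
#' count toward the quota. This emulates enrolment- and reagent-driven
#' genotyping patterns in which the genotyped subsample differs per variant.
#'
#' @param chrt A [cohort()].
#' @param genotyped_counts Matrix/data frame with columns `cases`,
#'   `controls`, rows named by variant id.
#' @param seed Integer seed (the draw of who is missing is reproducible).
#' @return The cohort with missingness applied. Errors if any sample would
#'   end up with no genotyped variant at all.
#' @export
inject_missingness <- function(chrt, genotyped_counts, seed = NULL) {
  stopifnot(inherits(chrt, "cohort"))
  gc_ <- as.matrix(as.data.frame(genotyped_counts)[, c("cases", "controls")])
  rownames(gc_) <- rownames(as.data.frame(genotyped_counts))
  n1 <- sum(chrt$phenotype == 1L); n0 <- sum(chrt$phenotype == 0L)
  if (any(gc_[, "cases"] > n1) || any(gc_[, "controls"] > n0)) {
    stop("configuration error: genotyped_counts exceed group sizes")
  }
  dos <- chrt$dosage
  local_seed(seed, {
    for (v in rownames(gc_)) {
      if (!v %in% colnames(dos)) {
        stop("configuration error: variant ", v, " not in cohort")
      }
      for (grp in c(1L, 0L)) {
        rows <- which(chrt$phenotype == grp)
        target <- if (grp == 1L) gc_[v, "cases"] else gc_[v, "controls"]
        n_missing_quota <- length(rows) - target
        already <- rows[is.na(dos[rows, v])]
        extra <- n_missing_quota - length(already)
        if (extra < 0) {
          stop("configuration error: variant ", v,
               " already has fewer genotyped samples than requested")
        }
        if (extra > 0) {
          candidates <- rows[!is.na(dos[rows, v])]
          drop_rows <- candidates[sample.int(length(candidates), extra)]
          dos[drop_rows, v] <- NA_real_
        }
      }
    }
    NULL
  })
  all_missing <- rowSums(!is.na(dos)) == 0
  if (any(all_missing)) {
    stop("missingness pattern leaves ", sum(all_missing),
         " sample(s) with no genotyped variant")
  }
  cohort(chrt$sample_ids, chrt$phenotype, dos)
}

#' Template simulation configuration for the REPLIK case-control study
#'
#' Returns a frequency-matched configuration preloaded with the printed
#' structure of the REPLIK (Recurrent Pregnancy Loss in Kiev) sample:
#' 114 idiopathic-RPL cases and 106 controls, the per-group effect-allele
#' frequencies of the 12 scoring variants, and the per-variant numbers of
#' genotyped cases and controls (genotyping depended on enrolment time and
#' reagent availability, so the genotyped subsample differs per variant —
#' e.g. 75 cases / 46 controls for rs6046 but the full 114/106 for
#' rs1800896).
#'
#' @param seed Integer seed stored in the config.
#' @return A `sim_config` in frequency-matched mode with `genotyped_counts`.
#' @export
replik_template_config <- function(seed = 1L) {
  ids <- c("rs1799963", "rs6025", "rs6046", "rs1126643", "rs2234693",
           "rs1042714", "Intron-4 VNTR", "rs1799752", "rs1801133",
           "14718", "rs2227306", "rs1800896")
  eaf_cases <- c(0.018, 0.018, 0.89, 0.63, 0.49, 0.60, 0.83, 0.52, 0.30,
                 0.59, 0.40, 0.59)
  eaf_controls <- c(0.011, 0.022, 0.85, 0.54, 0.55, 0.51, 0.80, 0.53, 0.24,
                    0.56, 0.37, 0.49)
  names(eaf_cases) <- names(eaf_controls) <- ids
  counts <- data.frame(
    cases = c(110L, 114L, 75L, 81L, 110L, 81L, 102L, 100L, 114L,
              106L, 114L, 114L),
    controls = c(46L, 46L, 46L, 46L, 106L, 46L, 46L, 46L, 46L,
                 106L, 106L, 106L),
    row.names = ids
  )
  simulation_config(n_cases = 114, n_controls = 106,
                    mode = "frequency_matched",
                    eaf_cases = eaf_cases, eaf_controls = eaf_controls,
                    genotyped_counts = counts, seed = seed)
}

#' Simulate the REPLIK template cohort
#'
#' Convenience wrapper: generates the frequency-matched cohort of
#' [replik_template_config()] and applies its per-variant genotyped-count
#' pattern via [inject_missingness()].
#'
#' @param seed Integer seed.
#' @return A [cohort()] of 114 cases and 106 controls over 12 variants.
#' @export
simulate_replik_template <- function(seed = 1L) {
  config <- replik_template_config(seed)
  chrt <- simulate_frequency_matched(config)
  # A distinct derived stream keeps genotype draws and missingness draws
  # independent while staying reproducible from the one seed.
  inject_missingness(chrt, config$genotyped_counts,
                     seed = (config$seed + 1000003L) %% .Machine$integer.max)
}
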