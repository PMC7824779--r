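# Per-variant case-control association under the log-additive model.

#' Effect-allele frequency within a phenotype group
#'
#' Complete-case frequency: missing dosages are excluded from both numerator
#' and denominator, so the EAF refers to the genotyped subsample of the
#' group.
#'
#' @param chrt A [cohort()].
#' @param variant_id Variant (dosage column) name.
#' @param group `"cases"` or `"controls"`.
#' @return `sum(dosage) / (2 * n_genotyped)` within the group.
#' @export
eaf <- function(chrt, variant_id, group = c("cases", "controls")) {
  group <- match.arg(group)
  stopifnot(inherits(chrt, "cohort"))
  if (!variant_id %in% colnames(chrt$dosage)) {
    stop("variant ", variant_id, " not in cohort")
  }
  d <- chrt$dosage[chrt$phenotype == (group == "cases"), variant_id]
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    stop("undefined frequency: no genotyped ", group, " for ", variant_id)
  }
  sum(d) / (2 * length(d))
}

# One logistic fit of y on a single continuous covariate x with Wald
# inference. Convergence tolerance 1e-8 on the deviance, max 100 IRLS
# iterations. Separation and constant covariates are flagged, not silently
# reported as huge estimates.
fit_logistic_wald <- function(y, x, level = 0.95) {
  status <- "ok"
  keep <- !is.na(x) & !is.na(y)
  y <- y[keep]; x <- x[keep]
  if (sum(y == 1L) < 1 || sum(y == 0L) < 1) {
    return(list(n_cases = sum(y == 1L), n_controls = sum(y == 0L),
                beta = NA_real_, se = NA_real_, or_ = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                status = "single_class"))
  }
  if (length(unique(x)) < 2) {
    return(list(n_cases = sum(y == 1L), n_controls = sum(y == 0L),
                beta = NA_real_, se = NA_real_, or_ = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                status = "constant_covariate"))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) {
    stop("logistic fit did not converge within 100 iterations")
  }
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  if (separated || se > 100) status <- "separation"
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(n_cases = sum(y == 1L), n_controls = sum(y == 0L),
       beta = beta, se = se, or_ = exp(beta),
       ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p = 2 * stats::pnorm(-abs(beta / se)), status = status)
}

#' Single-variant log-additive logistic association
#'
#' Maximum-likelihood logistic regression of case status on effect-allele
#' dosage, the log-additive model standard in genome-wide association
#' studies: each extra copy of the effect allele multiplies the odds of
#' disease by a constant factor `exp(beta)`. The fit is complete-case for
#' this variant (no imputation), so the effective sample size varies across
#' variants when genotyping is incomplete. Inference is Wald: the standard
#' error comes from the observed information at the MLE, the confidence
#' interval is `exp(beta +/- z * se)` and the p-value is from the two-sided
#' normal test of `beta / se`. Raw (nominal) p-values are reported, with no
#' multiple-testing correction.
#'
#' @param chrt A [cohort()].
#' @param variant_id Variant name.
#' @param level Confidence level (default 0.95).
#' @return A one-row data frame with `variant_id`, complete-case `n_cases`
#'   and `n_controls`, group EAFs, `beta` (the estimated allelic effect,
#'   log-odds per effect-allele copy), `se`, `or_`, `ci_low`, `ci_high`, `p`
#'   and a `status` column (`"ok"`, or a diagnostic flag such as
#'   `"separation"` or `"constant_covariate"` with `NA` estimates where the
#'   MLE is not interior).
#' @export
fit_logistic_dosage <- function(chrt, variant_id, level = 0.95) {
  stopifnot(inherits(chrt, "cohort"))
  if (!variant_id %in% colnames(chrt$dosage)) {
    stop("variant ", variant_id, " not in cohort")
  }
  d <- chrt$dosage[, variant_id]
  res <- fit_logistic_wald(chrt$phenotype, d, level = level)
  ec <- tryCatch(eaf(chrt, variant_id, "cases"), error = function(e) NA_real_)
  e0 <- tryCatch(eaf(chrt, variant_id, "controls"), error = function(e) NA_real_)
  data.frame(variant_id = variant_id,
             n_cases = res$n_cases, n_controls = res$n_controls,
             eaf_cases = ec, eaf_controls = e0,
             beta = res$beta, se = res$se, or_ = res$or_,
             ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
             status = res$status, stringsAsFactors = FALSE)
}

#' Per-variant association table over a panel
#'
#' Runs [fit_logistic_dosage()] for every non-excluded panel variant,
#' complete-case per variant, so the per-row sample sizes reflect the
#' genotyped subsamples. A variant that cannot be fitted (e.g. constant
#' dosage) is kept in the table with its diagnostic status rather than
#' aborting the rest.
#'
#' @param chrt A [cohort()].
#' @param panel A `variant_panel`; LD-excluded entries are dropped first.
#' @param level Confidence level.
#' @return A data frame with one row per scored variant, the panel's allele
#'   and position columns, and the association columns of
#'   [fit_logistic_dosage()].
#' @export
run_panel_association <- function(chrt, panel, level = 0.95) {
  panel12 <- apply_ld_exclusion(panel)
  absent <- setdiff(panel12$variant_id, colnames(chrt$dosage))
  if (length(absent) > 0) {
    stop("panel variants absent from cohort: ", paste(absent, collapse = ", "))
  }
  rows <- lapply(panel12$variant_id, function(v) {
    tryCatch(fit_logistic_dosage(chrt, v, level = level),
             error = function(e) {
               data.frame(variant_id = v, n_cases = NA_integer_,
                          n_controls = NA_integer_, eaf_cases = NA_real_,
                          eaf_controls = NA_real_, beta = NA_real_,
                          se = NA_real_, or_ = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          status = paste("error:", conditionMessage(e)),
                          stringsAsFactors = FALSE)
             })
  })
  out <- do.call(rbind, rows)
  meta <- panel12[match(out$variant_id, panel12$variant_id),
                  c("locus", "chrom_pos", "effect_allele", "other_allele")]
  out <- cbind(meta, out)
  rownames(out) <- NULL
  out
}

#' Write an association table as TSV
#'
#' Columns mirror the conventional candidate-gene results layout:
#' variant, position, alleles, per-group EAFs and Ns, the estimated allelic
#' effect, OR with CI bounds, p and status. Full-precision values are
#' written; `NA` marks unavailable cells.
#'
#' @param assoc A data frame from [run_panel_association()].
#' @param path Output file path.
#' @export
write_assoc_table <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
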