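# Weighted genetic risk scores with the per-person missingness correction.

#' Compute per-sample genetic risk scores
#'
#' @description
#' The raw score of sample i is the weighted sum of effect-allele dosages
#' over the variants genotyped in that sample,
#' `raw_i = sum_j w_j * d_ij` (missing variants contribute nothing). Because
#' the genotyped subset differs across individuals, raw scores are not
#' comparable between people genotyped at different numbers of variants; the
#' corrected score rescales by the fraction genotyped:
#'
#' `corrected_i = raw_i * M_total / m_i`
#'
#' where `M_total` is the panel size (12 for the default RPL panel after LD
#' exclusion) and `m_i` the number of scored variants genotyped in sample i.
#' Individuals genotyped at fewer variants thus have their partial score
#' scaled up. For a fully genotyped sample the factor is 1 and
#' corrected = raw; under unit weights the corrected score of a fully
#' genotyped sample is the integer risk-allele count.
#'
#' Samples with no genotyped scored variant cannot be scored; they are
#' dropped with a warning and listed in the `excluded` element.
#'
#' @param chrt A [cohort()].
#' @param weights A `weight_scheme` from [build_weight_scheme()], or a named
#'   numeric vector of log-odds weights. Every scored variant must have a
#'   weight; scoring is restricted to the weighted variants.
#' @param M_total Total panel size used in the correction factor; defaults
#'   to the number of weighted variants.
#' @return A `score_set`: list with `scores` (data frame `sample_id`,
#'   `m_genotyped`, `raw_score`, `corrected_score`), `M_total`, `scheme`,
#'   and `excluded` (sample ids dropped for having no genotyped variant).
#' @examples
#' chrt <- simulate_replik_template(seed = 7)
#' w <- build_weight_scheme(apply_ld_exclusion(build_default_panel()), "unit")
#' ss <- compute_grs(chrt, w)
#' head(ss$scores)
#' @export
compute_grs <- function(chrt, weights, M_total = NULL) {
  stopifnot(inherits(chrt, "cohort"))
  if (inherits(weights, "weight_scheme")) {
    scheme <- weights$scheme
    w <- weights$weights
  } else {
    scheme <- "custom"
    w <- weights
    if (is.null(names(w))) stop("weights must be named by variant_id")
  }
  absent <- setdiff(names(w), colnames(chrt$dosage))
  if (length(absent) > 0) {
    stop("configuration error: weighted variant(s) absent from cohort: ",
         paste(absent, collapse = ", "))
  }
  if (is.null(M_total)) M_total <- length(w)
  d <- chrt$dosage[, names(w), drop = FALSE]
  genotyped <- !is.na(d)
  m <- rowSums(genotyped)
  d0 <- d; d0[!genotyped] <- 0
  raw <- drop(d0 %*% w)

  unscorable <- m == 0
  if (any(unscorable)) {
    warning(sum(unscorable), " sample(s) with no genotyped scored variant ",
            "excluded from scoring")
  }
  keep <- !unscorable
  # m == M_total must leave the score bit-identical, not just within rounding
  corrected <- ifelse(m[keep] == M_total, raw[keep],
                      raw[keep] * M_total / m[keep])
  scores <- data.frame(sample_id = chrt$sample_ids[keep],
                       m_genotyped = as.integer(m[keep]),
                       raw_score = raw[keep],
                       corrected_score = corrected,
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, M_total = as.integer(M_total),
                 scheme = scheme,
                 excluded = chrt$sample_ids[unscorable]),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("Genetic risk scores (", x$scheme, " weights, M = ", x$M_total, "): ",
      nrow(x$scores), " samples scored", sep = "")
  if (length(x$excluded) > 0) cat(",", length(x$excluded), "excluded")
  cat("\n")
  print(utils::head(x$scores))
  invisible(x)
}

#' Association between the risk score and case status
#'
#' Logistic regression of phenotype on the corrected score as a single
#' continuous covariate, with Wald inference: the odds ratio is per one unit
#' of the corrected score (the score enters on its raw corrected scale; no
#' standardisation unless `standardize = TRUE`, in which case the OR is per
#' standard deviation of the corrected score).
#'
#' @param scores A `score_set` from [compute_grs()].
#' @param phenotype Named or positionally aligned 0/1 vector, or a
#'   [cohort()] from which phenotypes are matched by `sample_id`.
#' @param standardize Divide the corrected score by its sample SD before
#'   fitting (off by default).
#' @param level Confidence level.
#' @return One-row data frame: `scheme`, `n_cases`, `n_controls`, `beta`,
#'   `se`, `or_`, `ci_low`, `ci_high`, `p`, `status`.
#' @export
grs_association <- function(scores, phenotype, standardize = FALSE,
                            level = 0.95) {
  stopifnot(inherits(scores, "score_set"))
  if (inherits(phenotype, "cohort")) {
    phenotype <- phenotype$phenotype[match(scores$scores$sample_id,
                                           phenotype$sample_ids)]
  } else if (!is.null(names(phenotype))) {
    phenotype <- phenotype[scores$scores$sample_id]
  }
  if (length(phenotype) != nrow(scores$scores)) {
    stop("phenotype does not align with scored samples")
  }
  x <- scores$scores$corrected_score
  if (standardize) x <- x / stats::sd(x)
  res <- fit_logistic_wald(as.integer(phenotype), x, level = level)
  data.frame(scheme = scores$scheme,
             n_cases = res$n_cases, n_controls = res$n_controls,
             beta = res$beta, se = res$se, or_ = res$or_,
             ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
             status = res$status, stringsAsFactors = FALSE)
}

#' Risk-score sensitivity analysis over the three weighting schemes
#'
#' Computes and tests the GRS under the published-mixed weights (headline),
#' the all-study weights and the unweighted (unit) scheme, as a sensitivity
#' check that conclusions do not hinge on the weighting source.
#'
#' @param chrt A [cohort()].
#' @param panel12 A `variant_panel` after LD exclusion.
#' @param study_betas Named in-study log-odds estimates, typically the
#'   `beta` column of [run_panel_association()] on the same cohort.
#' @param standardize Passed to [grs_association()].
#' @return List with `table` (3-row data frame, one per scheme) and
#'   `scores` (named list of the three `score_set`s).
#' @export
run_grs_sensitivity <- function(chrt, panel12, study_betas,
                                standardize = FALSE) {
  schemes <- c("published_mixed", "study", "unit")
  score_sets <- lapply(schemes, function(s) {
    w <- build_weight_scheme(panel12, s, study_betas = study_betas)
    compute_grs(chrt, w, M_total = nrow(panel12))
  })
  names(score_sets) <- schemes
  rows <- lapply(score_sets, grs_association, phenotype = chrt,
                 standardize = standardize)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, scores = score_sets)
}

#' Write per-sample scores as TSV
#'
#' @param scores A `score_set`.
#' @param chrt Optional [cohort()] supplying the phenotype column.
#' @param path Output path.
#' @export
write_score_table <- function(scores, path, chrt = NULL) {
  out <- scores$scores
  if (!is.null(chrt)) {
    out$phenotype <- chrt$phenotype[match(out$sample_id, chrt$sample_ids)]
    out <- out[, c("sample_id", "phenotype", "m_genotyped",
                   "raw_score", "corrected_score")]
  }
  out$scheme <- scores$scheme
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
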