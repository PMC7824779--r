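#' Variant panel for recurrent pregnancy loss risk scoring
#'
#' @description
#' `build_default_panel()` returns the 13-variant candidate panel used for
#' combined-variant risk scoring of recurrent pregnancy loss (RPL): ten SNPs,
#' the ACE insertion/deletion rs1799752 (alleles D/I), the ENOS intron-4
#' VNTR (alleles B/A) and the IL6 tandem repeat 14718 (alleles G/C), spanning
#' blood coagulation (F2, F5, F7, GP1A), hormonal regulation (ESR1, ADRB2),
#' endometrium/placental function (ENOS, ACE), folate metabolism (MTHFR) and
#' inflammatory response (IL6, IL8, IL10).
#'
#' Each entry carries the effect allele whose dosage (0/1/2 copies) enters the
#' model, the previously published odds ratio where a prior RPL association
#' exists (absent for F7, GP1A, ADRB2 and IL8), the ancestry of the study the
#' OR was published in, the weight-source rule used by the published-mixed
#' weighting scheme, and a linkage-disequilibrium exclusion flag. One IL10
#' variant (rs1800872) is flagged for exclusion because of high LD with
#' rs1800896; risk scores are computed over the remaining 12 variants.
#'
#' Non-SNP variants are coded as ordinary biallelic dosages of the effect
#' allele, exactly like SNPs: each has a well-defined effect/other allele
#' pair and per-group effect-allele frequency.
#'
#' @return A `variant_panel`: a data frame with one row per variant and
#'   columns `variant_id`, `locus`, `chrom_pos`, `effect_allele`,
#'   `other_allele`, `variant_class` (`"SNP"`, `"indel"`, `"VNTR"` or
#'   `"STR"`), `published_or` (`NA` where no prior RPL association exists),
#'   `population` (`"european"`, `"non_european"`, `"multi_ethnic"` or
#'   `"none"`), `weight_source` (`"published"` or `"study"`) and
#'   `ld_excluded` (logical).
#' @examples
#' panel <- build_default_panel()
#' nrow(panel)                      # 13
#' sum(is.na(panel$published_or))   # 4 variants with no prior RPL estimate
#' @export
build_default_panel <- function() {
  panel <- data.frame(
    variant_id = c(
      "rs1799963", "rs6025", "rs6046", "rs1126643", "rs2234693",
      "rs1042714", "Intron-4 VNTR", "rs1799752", "rs1801133", "14718",
      "rs2227306", "rs1800896", "rs1800872"
    ),
    locus = c(
      "F2", "F5", "F7", "GP1A", "ESR1", "ADRB2", "ENOS", "ACE",
      "MTHFR", "IL6", "IL8", "IL10", "IL10"
    ),
    chrom_pos = c(
      "11:46761055", "1:169519049", "13:113773159", "5:52347369",
      "6:152163335", "5:148206473", "15:35147732-35262040", "17:61565890",
      "1:11856378", "7:22766840", "4:74607055", "1:206946897", NA
    ),
    effect_allele = c("A", "A", "G", "C", "T", "C", "B", "D", "T", "G",
                      "T", "A", "T"),
    other_allele = c("G", "G", "A", "T", "C", "G", "A", "I", "C", "C",
                     "C", "G", "G"),
    variant_class = c("SNP", "SNP", "SNP", "SNP", "SNP", "SNP", "VNTR",
                      "indel", "SNP", "STR", "SNP", "SNP", "SNP"),
    published_or = c(2.00, 2.5, NA, NA, 1.10, NA, 1.005, 2.06, 1.25,
                     1.214, NA, 1.27, 3.01),
    population = c("european", "multi_ethnic", "none", "none",
                   "non_european", "none", "non_european", "multi_ethnic",
                   "multi_ethnic", "multi_ethnic", "none", "non_european",
                   "european"),
    weight_source = c("published", "published", "study", "study",
                      "published", "study", "study", "published",
                      "published", "study", "study", "study", "study"),
    ld_excluded = c(rep(FALSE, 12), TRUE),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("variant_panel", "data.frame")
  validate_panel(panel)
  panel
}

#' Validate a variant panel
#'
#' Checks structural invariants of a panel data frame: required columns,
#' distinct effect/other alleles, a known variant class and no duplicated
#' variant ids. Called by the constructors and readers; available directly
#' for user-supplied panels.
#'
#' @param panel A data frame with the `variant_panel` columns.
#' @return The panel, invisibly, with class `variant_panel` attached.
#' @export
validate_panel <- function(panel) {
  required <- c("variant_id", "locus", "effect_allele", "other_allele",
                "variant_class", "published_or", "ld_excluded")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("malformed panel: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$variant_id)) {
    stop("malformed panel: duplicated variant_id")
  }
  bad <- panel$effect_allele == panel$other_allele
  if (any(bad)) {
    stop("malformed panel: effect allele equals other allele for ",
         paste(panel$variant_id[bad], collapse = ", "))
  }
  known_class <- panel$variant_class %in% c("SNP", "indel", "VNTR", "STR")
  if (!all(known_class)) {
    stop("malformed panel: unknown variant_class for ",
         paste(panel$variant_id[!known_class], collapse = ", "))
  }
  or_ok <- is.na(panel$published_or) | panel$published_or > 0
  if (!all(or_ok)) stop("malformed panel: published_or must be positive")
  if (!inherits(panel, "variant_panel")) {
    class(panel) <- c("variant_panel", class(panel))
  }
  invisible(panel)
}

#' Drop LD-flagged variants from a panel
#'
#' Removes panel entries flagged `ld_excluded`, the rule-based analogue of
#' pruning one member of each high-LD pair before score construction. In the
#' default panel this drops rs1800872, which is in high LD with rs1800896
#' (r-squared 0.26 in Europeans, from external reference data), leaving the
#' 12-variant scoring panel.
#'
#' @param panel A `variant_panel` data frame.
#' @return The panel restricted to rows with `ld_excluded == FALSE`.
#' @examples
#' nrow(apply_ld_exclusion(build_default_panel()))  # 12
#' @export
apply_ld_exclusion <- function(panel) {
  validate_panel(panel)
  # The default panel's exclusion resolves the IL10 rs1800872/rs1800896 pair.
  # A panel recognizably derived from the default one (all ids drawn from it)
  # that carries neither IL10 variant is malformed, not merely exclusion-free;
  # unrelated user panels are passed through.
  il10 <- c("rs1800872", "rs1800896")
  rpl_ids <- c("rs1799963", "rs6025", "rs6046", "rs1126643", "rs2234693",
               "rs1042714", "Intron-4 VNTR", "rs1799752", "rs1801133",
               "14718", "rs2227306", il10)
  if (nrow(panel) > 0 && all(panel$variant_id %in% rpl_ids) &&
      !any(il10 %in% panel$variant_id)) {
    stop("malformed panel: both IL10 variants absent from the RPL panel")
  }
  out <- panel[!panel$ld_excluded, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_panel", "data.frame")
  out
}

#' Convert an odds ratio to a log-odds score weight
#'
#' Risk-score weights are beta coefficients on the log-odds scale, so a
#' published per-allele odds ratio contributes `log(OR)` per copy of the
#' effect allele.
#'
#' @param or_value Positive odds ratio(s).
#' @return `log(or_value)`.
#' @examples
#' weight_from_or(1.64)  # 0.49 to 2 dp
#' weight_from_or(1.0)   # 0: null effect
#' @export
weight_from_or <- function(or_value) {
  if (!is.numeric(or_value) || any(!is.finite(or_value)) || any(or_value <= 0)) {
    stop("or_value must be a positive finite number")
  }
  log(or_value)
}

#' Build a weighting scheme for the scoring panel
#'
#' @description
#' Constructs per-variant log-odds weights under one of three schemes:
#'
#' * `"published_mixed"` — the headline scheme. Variants with a prior RPL
#'   odds ratio from a population where that estimate is transferable
#'   (F2, F5, ESR1, ACE, MTHFR) take `log(published OR)`; the remaining
#'   seven (F7, GP1A, ADRB2, ENOS, IL6, IL8, IL10) take the in-study
#'   per-variant effect estimates, either because no prior RPL association
#'   was ever published or because the published estimate comes from an
#'   ethnically discordant study.
#' * `"study"` — every weight is the in-study estimate (sensitivity check).
#' * `"unit"` — every weight is 1, giving an unweighted risk-allele count.
#'
#' @param panel12 A `variant_panel` after LD exclusion (weights are defined
#'   for exactly its variants).
#' @param scheme One of `"published_mixed"`, `"study"`, `"unit"`.
#' @param study_betas Named numeric vector of in-study log-odds estimates
#'   (names are variant ids). Required for every variant whose source
#'   resolves to `"study"`; ignored for `"unit"`.
#' @return A `weight_scheme`: list with elements `scheme`, `weights`
#'   (named numeric, log-odds units) and `source` (named character,
#'   `"published"`, `"study"` or `"unit"` per variant).
#' @examples
#' panel12 <- apply_ld_exclusion(build_default_panel())
#' unit <- build_weight_scheme(panel12, "unit")
#' all(unit$weights == 1)
#' @export
build_weight_scheme <- function(panel12,
                                scheme = c("published_mixed", "study", "unit"),
                                study_betas = NULL) {
  scheme <- match.arg(scheme)
  validate_panel(panel12)
  if (any(panel12$ld_excluded)) {
    stop("panel passed to build_weight_scheme still contains LD-excluded variants; ",
         "apply_ld_exclusion() first")
  }
  ids <- panel12$variant_id

  source <- switch(scheme,
    unit = rep("unit", length(ids)),
    study = rep("study", length(ids)),
    published_mixed = {
      if (!is.null(panel12$weight_source)) {
        panel12$weight_source
      } else {
        # panels without an explicit rule: published where an OR exists
        ifelse(is.na(panel12$published_or), "study", "published")
      }
    }
  )
  names(source) <- ids

  weights <- numeric(length(ids))
  names(weights) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    weights[i] <- switch(source[i],
      unit = 1,
      published = {
        if (is.na(panel12$published_or[i])) {
          stop("configuration error: no published OR for published-source variant ", id)
        }
        weight_from_or(panel12$published_or[i])
      },
      study = {
        if (is.null(study_betas) || is.na(study_betas[id]) ||
            !(id %in% names(study_betas))) {
          stop("configuration error: missing study beta for study-source variant ", id)
        }
        unname(study_betas[id])
      },
      stop("unknown weight source '", source[i], "' for variant ", id)
    )
  }

  structure(list(scheme = scheme, weights = weights, source = source),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Weight scheme:", x$scheme, "(", length(x$weights), "variants )\n")
  print(data.frame(variant_id = names(x$weights),
                   weight = round(unname(x$weights), 4),
                   source = unname(x$source)), row.names = FALSE)
  invisible(x)
}

#' In-study effect estimates printed for the 12-variant RPL panel
#'
#' Per-variant estimated allelic effects (log odds ratios) from the REPLIK
#' case-control sample, as used for the study-source weights of the
#' published-mixed scheme and for the all-study sensitivity scheme. These are
#' the per-variant complete-case logistic estimates on each variant's
#' genotyped subsample.
#'
#' @return Named numeric vector of length 12 (names are variant ids).
#' @export
replik_study_betas <- function() {
  c("rs1799963" = 0.49, "rs6025" = -0.22, "rs6046" = 0.34,
    "rs1126643" = 0.35, "rs2234693" = -0.18, "rs1042714" = 0.38,
    "Intron-4 VNTR" = 0.15, "rs1799752" = -0.048, "rs1801133" = 0.33,
    "14718" = 0.11, "rs2227306" = 0.11, "rs1800896" = 0.47)
}

#' Read / write a variant panel as TSV
#'
#' Tab-separated panel files have a mandatory header with columns
#' `variant_id`, `locus`, `effect_allele`, `other_allele`, `variant_class`,
#' `published_or`, `population`, `ld_excluded` (0/1) and optionally
#' `chrom_pos` and `weight_source`; empty or `"."` fields are absent values.
#'
#' @param path File path.
#' @return `read_panel_table()` returns a validated `variant_panel`.
#' @export
read_panel_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."))
  required <- c("variant_id", "locus", "effect_allele", "other_allele",
                "variant_class", "published_or", "ld_excluded")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("panel file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$ld_excluded <- as.logical(as.integer(raw$ld_excluded))
  raw$published_or <- as.numeric(raw$published_or)
  if (is.null(raw$population)) raw$population <- "none"
  if (is.null(raw$chrom_pos)) raw$chrom_pos <- NA_character_
  validate_panel(raw)
  class(raw) <- c("variant_panel", "data.frame")
  raw
}

#' @rdname read_panel_table
#' @param panel A `variant_panel`.
#' @export
write_panel_table <- function(panel, path) {
  validate_panel(panel)
  out <- as.data.frame(panel)
  out$ld_excluded <- as.integer(out$ld_excluded)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
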