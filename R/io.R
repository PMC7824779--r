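# Genotype-table and VCF import, and the end-to-end pipeline driver.

#' Read / write a genotype dosage table
#'
#' Tab-separated, one row per sample: `sample_id`, `phenotype` (0/1), then
#' one column per variant holding the effect-allele dosage 0/1/2 or `NA`.
#' Header row mandatory; UTF-8. Unknown dosage tokens and duplicate sample
#' ids are rejected with the offending row/column named.
#'
#' @param path File path.
#' @return `read_genotype_table()` returns a validated [cohort()].
#' @export
read_genotype_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(raw))) {
    stop("genotype file ", path, " must start with sample_id and phenotype columns")
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id in ", path, ": ",
         raw$sample_id[duplicated(raw$sample_id)][1])
  }
  variant_cols <- setdiff(names(raw), c("sample_id", "phenotype"))
  if (length(variant_cols) == 0) stop("no variant columns in ", path)
  dos <- as.matrix(raw[, variant_cols, drop = FALSE])
  mode(dos) <- "numeric"
  bad <- which(!(is.na(dos) | dos %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid dosage '", dos[bad[1, , drop = FALSE]], "' at row ",
         bad[1, 1], " (sample ", raw$sample_id[bad[1, 1]], "), column ",
         variant_cols[bad[1, 2]])
  }
  if (!all(raw$phenotype %in% c(0, 1))) {
    stop("phenotype column must be 0/1 in ", path)
  }
  cohort(raw$sample_id, raw$phenotype, dos)
}

#' @rdname read_genotype_table
#' @param chrt A [cohort()].
#' @export
write_genotype_table <- function(chrt, path) {
  stopifnot(inherits(chrt, "cohort"))
  out <- data.frame(sample_id = chrt$sample_ids,
                    phenotype = chrt$phenotype,
                    chrt$dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Import genotypes from a VCF file
#'
#' Builds a [cohort()] from biallelic VCF records: the dosage is the count
#' of the effect allele in the GT field; missing genotypes (`./.`) become
#' missing dosages. Effect alleles are matched against REF/ALT through an
#' explicit allele map — no strand flipping is attempted. Multiallelic
#' records, and records whose mapped effect allele matches neither REF nor
#' ALT, are skipped with a warning.
#'
#' @param path VCF file path (requires the vcfR package).
#' @param effect_allele_map Named character vector: variant id (VCF ID
#'   column) to effect allele.
#' @param phenotype_table Data frame with `sample_id` and `phenotype` (0/1)
#'   covering every VCF sample.
#' @return A [cohort()].
#' @export
import_vcf <- function(path, effect_allele_map, phenotype_table) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(vcf)),
                dimnames = dimnames(vcfR::getFIX(vcf)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)

  keep_rows <- list()
  for (i in seq_len(nrow(fix))) {
    id <- fix[i, "ID"]
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (is.na(id) || !(id %in% names(effect_allele_map))) next
    if (grepl(",", alt, fixed = TRUE)) {
      warning("skipping multiallelic record ", id)
      next
    }
    ea <- effect_allele_map[[id]]
    if (!(ea %in% c(ref, alt))) {
      warning("skipping ", id, ": effect allele ", ea,
              " matches neither REF nor ALT")
      next
    }
    ea_index <- if (ea == ref) "0" else "1"
    g <- gt[i, ]
    dosage <- vapply(g, function(cell) {
      if (is.na(cell)) return(NA_real_)
      alleles <- strsplit(cell, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == ea_index)
    }, numeric(1))
    keep_rows[[id]] <- dosage
  }
  if (length(keep_rows) == 0) stop("no usable biallelic records in ", path)
  dos <- do.call(cbind, keep_rows)
  rownames(dos) <- samples
  ph <- phenotype_table$phenotype[match(samples, phenotype_table$sample_id)]
  if (any(is.na(ph))) {
    stop("phenotype missing for sample(s): ",
         paste(samples[is.na(ph)], collapse = ", "))
  }
  cohort(samples, ph, dos)
}

#' Run the full panel analysis pipeline
#'
#' @description
#' Executes the analysis sequence end to end — cohort (simulated or read from
#' file), per-variant association table, risk scores and GRS association
#' under the three weighting schemes, and ROC evaluation of each score — and
#' writes every table plus a run manifest into `out_dir`. With a fixed
#' simulation seed the outputs are byte-identical across runs.
#'
#' Files written: `cohort.tsv` (simulated input echo), `association.tsv`
#' (one row per scored variant), `grs_sensitivity.tsv` (one row per
#' weighting scheme), `scores_<scheme>.tsv`,
#' `roc_<scheme>_points.tsv` / `_summary.tsv`, and `manifest.tsv`.
#'
#' @param sim_config A `sim_config` (simulated input), or `NULL`.
#' @param genotypes Path to a genotype TSV (file input), or `NULL`. Exactly
#'   one of `sim_config` / `genotypes` must be given.
#' @param panel A `variant_panel` (default [build_default_panel()]).
#' @param out_dir Output directory (created if absent).
#' @param ci AUC confidence-interval method, `"delong"` or `"bootstrap"`.
#' @param standardize Standardise the score before the GRS fit.
#' @return Invisibly, a list with the cohort, association table, sensitivity
#'   table, score sets and ROC curves.
#' @export
run_pipeline <- function(sim_config = NULL, genotypes = NULL,
                         panel = build_default_panel(), out_dir,
                         ci = "delong", standardize = FALSE) {
  if (is.null(sim_config) == is.null(genotypes)) {
    stop("configuration error: provide exactly one of sim_config or genotypes")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  validate_panel(panel)

  if (!is.null(sim_config)) {
    chrt <- simulate_frequency_matched(sim_config)
    if (!is.null(sim_config$genotyped_counts)) {
      chrt <- inject_missingness(
        chrt, sim_config$genotyped_counts,
        seed = (sim_config$seed + 1000003L) %% .Machine$integer.max)
    }
    write_genotype_table(chrt, file.path(out_dir, "cohort.tsv"))
  } else {
    chrt <- read_genotype_table(genotypes)
  }

  panel12 <- apply_ld_exclusion(panel)
  assoc <- run_panel_association(chrt, panel12)
  write_assoc_table(assoc, file.path(out_dir, "association.tsv"))

  study_betas <- stats::setNames(assoc$beta, assoc$variant_id)
  if (any(is.na(study_betas))) {
    stop("cannot build study weights: per-variant fit failed for ",
         paste(names(study_betas)[is.na(study_betas)], collapse = ", "))
  }
  sens <- run_grs_sensitivity(chrt, panel12, study_betas,
                              standardize = standardize)
  utils::write.table(sens$table, file.path(out_dir, "grs_sensitivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rocs <- list()
  for (scheme in names(sens$scores)) {
    ss <- sens$scores[[scheme]]
    write_score_table(ss, file.path(out_dir, paste0("scores_", scheme, ".tsv")),
                      chrt = chrt)
    ph <- chrt$phenotype[match(ss$scores$sample_id, chrt$sample_ids)]
    rc <- roc_curve(ss$scores$corrected_score, ph, ci = ci)
    write_roc_tables(rc, file.path(out_dir, paste0("roc_", scheme)))
    rocs[[scheme]] <- rc
  }

  manifest <- data.frame(
    key = c("package", "package_version", "input",
            "seed", "n_cases", "n_controls", "n_panel_variants",
            "n_scored_variants", "schemes", "ci_method", "standardize",
            "status"),
    value = c("grspanel", as.character(utils::packageVersion("grspanel")),
              if (is.null(genotypes)) "simulated" else genotypes,
              if (is.null(sim_config)) "NA" else as.character(sim_config$seed),
              sum(chrt$phenotype == 1L), sum(chrt$phenotype == 0L),
              nrow(panel), nrow(panel12),
              paste(names(sens$scores), collapse = ","), ci,
              as.character(standardize), "complete"),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(cohort = chrt, association = assoc,
                 grs_sensitivity = sens$table, scores = sens$scores,
                 roc = rocs))
}
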