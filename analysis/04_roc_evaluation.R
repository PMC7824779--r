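#!/usr/bin/env Rscript
# ROC evaluation of each risk score as a case/control classifier: empirical
# curve, trapezoid AUC with DeLong 95% CI, and the Youden best
# discriminating point.

library(grspanel)

chrt <- read_genotype_table("results/cohort.tsv")

summaries <- NULL
for (scheme in c("published_mixed", "study", "unit")) {
  sc <- utils::read.delim(paste0("results/scores_", scheme, ".tsv"))
  rc <- roc_curve(sc$corrected_score, sc$phenotype, ci = "delong")
  write_roc_tables(rc, paste0("results/roc_", scheme))
  cat("\n--", scheme, "weights --\n")
  print(rc)
  summaries <- rbind(summaries, data.frame(
    scheme = scheme, auc = rc$auc, ci_low = rc$auc_ci_low,
    ci_high = rc$auc_ci_high, best_threshold = rc$best_threshold,
    best_sensitivity = rc$best_sensitivity,
    best_specificity = rc$best_specificity))
}
utils::write.table(summaries, "results/roc_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

best <- summaries[which.max(summaries$auc), ]
message(sprintf(paste0(
  "Best-classifying scheme on this cohort: %s (AUC %.2f, 95%% CI %.2f-%.2f; ",
  "Youden point sensitivity %.0f%%, specificity %.0f%%)."),
  best$scheme, best$auc, best$ci_low, best$ci_high,
  100 * best$best_sensitivity, 100 * best$best_specificity))
message("ROC point sets and summary written under results/.")
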