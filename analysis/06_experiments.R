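#!/usr/bin/env Rscript
# Ablation experiments on the cleaned cohort:
#  (1) per-profile ablation at the 2-month width: which data profile
#      (clinical, treatment, life quality) predicts survival best on its own;
#  (2) timed vs untimed (no-sequence-mining) comparison on shared folds,
#      with a paired one-sided t-test over per-fold accuracies.

suppressPackageStartupMessages(library(ovsurvmine))

cohort <- attach_life_quality(read_cohort("results/cohort_clean"))
config <- experiment_config(widths = c(2, 6), folds = 10, seed = 0)

ablation <- run_profile_ablation(cohort, config, width = 2)
utils::write.csv(ablation$table, "results/profile_ablation.csv",
                 row.names = FALSE)
cat("best model per data profile (2-month width, 10-fold CV):\n")
print(ablation$best, row.names = FALSE, digits = 3)

seq_cmp <- run_sequence_ablation(cohort, config, model_name = "boosting")
utils::write.csv(seq_cmp$table, "results/sequence_comparison.csv",
                 row.names = FALSE)
tests <- lapply(seq_cmp$tests, function(t) t[c("t", "df", "p", "significant")])
jsonlite::write_json(tests, "results/sequence_ttests.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat("\ntimed vs untimed treatment encoding (boosting, shared folds):\n")
print(seq_cmp$table, row.names = FALSE, digits = 3)
cat("\npaired one-sided t-tests (timed > untimed), per width:\n")
for (w in names(seq_cmp$tests)) {
  t <- seq_cmp$tests[[w]]
  cat(sprintf("  width %s: t = %.3f, p = %.3f%s\n", w, t$t, t$p,
              if (isTRUE(t$significant)) " (significant at 0.05)" else ""))
}
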