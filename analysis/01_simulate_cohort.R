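#!/usr/bin/env Rscript
# Simulate the study cohort: 140 advanced ovarian cancer patients, ~42%
# 3-year survival, negative age/ECOG/CCI effects, a timed chemotherapy->CRS
# transition effect, and 5% MCAR missingness in the clinical attributes
# (plus a few missing outcome labels, so the cleaning step has work to do).
# Writes patients.csv / events.csv under results/cohort/.

suppressPackageStartupMessages(library(ovsurvmine))

spec <- cohort_spec(
  n_patients = 140,
  survival_prevalence = 0.4214,
  effect_coefficients = c(age = -0.4, ecog = -0.8, cci = -0.5),
  planted_pattern = default_planted_pattern(weight = 2),
  missing_rate = 0.05,
  label_missing_rate = 0.04,
  seed = 20260926
)

cohort <- inject_missingness(generate_cohort(spec), spec)
write_cohort(cohort, "results/cohort")

cat(sprintf("simulated %d patients, %d treatment events\n",
            nrow(cohort$patients), nrow(cohort$events)))
cat(sprintf("missing outcome labels: %d\n",
            sum(is.na(cohort$patients$survived_3yr))))
cat(sprintf("missing clinical cells: %d\n",
            sum(is.na(cohort$patients[, c("age", "ca125", "ascites",
                                          "grade", "stage", "histology")]))))
cat("wrote results/cohort/{patients,events}.csv\n")
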