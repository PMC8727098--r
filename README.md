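# ovsurvmine

Integrated 3-year survival prediction for advanced ovarian cancer cohorts
from three data profiles: clinical attributes, multi-line **treatment
sequences with inter-treatment time intervals**, and quality-of-life
measures (ECOG performance status and the Charlson Comorbidity Index).

The package is aimed at biostatisticians studying small retrospective
oncology cohorts where *when* the next line of therapy followed the
previous one may carry prognostic signal that treatment-presence encodings
miss.

## What it computes

1. **No-gap frequent substring mining.** Per-patient treatment sequences
   are mined with a level-wise GSP variant under a contiguity constraint:
   X → Y counts only when no therapy was interposed. A pattern is frequent
   when its per-patient support count reaches `ceiling(minsup · |DB|)`
   (default `minsup = 0.05`). A brute-force enumerator serves as oracle.
2. **Time-binned transition features.** Each frequent pair (X, Y) and bin
   width *w* (months) yields binary columns `X_Tk_Y`: Y immediately after X
   with gap in the half-open bin ((k−1)w, kw]; widths 1/2/3 months on a
   36-month horizon give 36/18/12 bins. Columns are kept when their
   information gain `Gain(A) = Info(D) − Info_A(D)` exceeds 0.
3. **Charlson Comorbidity Index.** Configurable weights (COPD +1,
   uncomplicated diabetes +1, end-organ diabetes +3, severer diabetes flag
   wins) plus a universal +2 base malignancy weight.
4. **Classification under stratified 10-fold CV.** AdaBoost implemented
   from its reweighting equations (round error = weight-sum over
   misclassified instances; vote = log((1−err)/err); correct weights scaled
   by err/(1−err), renormalised) over depth-limited tree weak learners,
   plus bagging, random forest, gradient boosting and logistic baselines.
   Metrics from pooled out-of-fold predictions: accuracy (%), sensitivity
   (positive class = survived), specificity, rank-statistic AUC.
5. **Experiments.** Interval-width sweeps, per-profile ablations, timed vs
   untimed comparisons on shared folds, and paired one-sided t-tests over
   per-fold accuracies.
6. **Synthetic cohorts.** A seeded generator with realistic clinical
   marginals, a first-order treatment grammar, a logistic outcome model
   with calibrated prevalence, plantable attribute and timed-transition
   effects, and MCAR missingness — so the whole pipeline is testable
   without any private data.

## Worked example

The numbered scripts under `analysis/` run the full narrative on a
simulated 140-patient cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort with planted effects + missingness
Rscript analysis/02_clinical_prep.R     # drop, impute, summarize
Rscript analysis/03_mine_sequences.R    # no-gap GSP at support 0.05
Rscript analysis/04_interval_features.R # 2-month bins + IG selection
Rscript analysis/05_classification.R    # width sweep x model suite
Rscript analysis/06_experiments.R       # ablations + paired t-tests
```

`02_clinical_prep.R` prints, for instance:

```
cleaned cohort: 134 patients (6 dropped), 42 cells imputed
3-year survival: 48/134 = 35.82%
ECOG groups show the expected declining survival trend:
 group  n survivors survival_rate_pct
     1 37        19             51.35
     2 42        15             35.71
     3 34        11             32.35
     4 15         3             20.00
     5  6         0              0.00
```

— the six patients without an outcome label are removed, missing clinical
cells are imputed class-conditionally, and survival declines monotonically
with worse performance status, reflecting the generator's planted negative
ECOG effect. `03_mine_sequences.R` then reports 18 frequent substrings,
led by `Surgery->Chemotherapy` (36/134 patients), and
`05_classification.R` cross-validates five models at five bin widths
(best cell in this run: 68.7% accuracy). At 140 patients the timed-vs-
untimed contrast is within fold noise (`06_experiments.R` prints the
paired t-tests); the package's tests show the same planted 2–6-month
chemotherapy→CRS effect is reliably recovered at 600 patients.

A minimal programmatic session:

```r
library(ovsurvmine)
spec <- cohort_spec(n_patients = 140,
                    planted_pattern = default_planted_pattern(), seed = 7)
cohort <- attach_life_quality(generate_cohort(spec))
db <- build_sequence_db(cohort)
patterns <- mine_frequent_substrings(db, minsup = 0.05)
timed <- build_timed_matrix(db, patterns, bin_scheme(2),
                            cohort$patients$survived_3yr)
sel <- select_by_ig(timed)
cross_validate(sel$features, model_spec("adaboost"), k = 10, seed = 1)
#> ov_cv: 10 folds | accuracy 58.6% | sensitivity 0.310 | specificity 0.780 | AUC 0.509
```

## Layout

```
R/                  package code (generator, cleaning, mining, features,
                    CCI, classifiers, experiment runners)
analysis/           numbered narrative drivers writing results/
scripts/acceptance.R  reference-value recomputation
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, design choices)
```
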