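## Experiment orchestration: interval-width sweep, per-profile ablation,
## timed vs untimed comparison, and paired significance testing.

#' Clinical profile feature matrix
#'
#' Numeric encodings for the six clinical attributes: age and CA-125 as-is,
#' ascites as 0/1, grade numeric, FIGO substage ordinal (3a < 3b < 3c < 4),
#' histology one-hot.
#'
#' @param cohort A cleaned `ov_cohort`.
#' @return Numeric matrix, one row per patient.
#' @export
clinical_feature_matrix <- function(cohort) {
  p <- cohort$patients
  stage_ord <- c("3a" = 1, "3b" = 2, "3c" = 3, "4" = 4)
  hist_levels <- sort(unique(p$histology))
  hist_cols <- sapply(hist_levels, function(h) as.numeric(p$histology == h))
  hist_cols <- matrix(hist_cols, nrow = nrow(p),
                      dimnames = list(p$patient_id,
                                      paste0("histology_", hist_levels)))
  x <- cbind(age = p$age, ca125 = p$ca125,
             ascites = as.numeric(p$ascites == "yes"),
             grade = as.numeric(p$grade),
             stage = as.numeric(stage_ord[p$stage]),
             hist_cols)
  rownames(x) <- p$patient_id
  x
}

#' Life-quality profile feature matrix (CCI and ECOG)
#'
#' @param cohort An `ov_cohort` with `cci` attached
#'   (see [attach_life_quality()]).
#' @return Numeric matrix with columns `cci` and `ecog`.
#' @export
life_quality_matrix <- function(cohort) {
  p <- cohort$patients
  if (is.null(p$cci)) {
    stop("cohort has no cci column; run attach_life_quality() first",
         call. = FALSE)
  }
  x <- cbind(cci = as.numeric(p$cci), ecog = as.numeric(p$ecog))
  rownames(x) <- p$patient_id
  x
}

#' Experiment configuration
#'
#' @param widths Time-bin widths (months) to sweep.
#' @param minsup Relative support threshold for sequence mining.
#' @param models Named list of [model_spec()]s.
#' @param folds Number of CV folds.
#' @param seed Fold-assignment seed.
#' @param horizon_months Follow-up horizon.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(widths = c(1, 2, 3, 4, 6), minsup = 0.05,
                              models = default_model_specs(), folds = 10,
                              seed = 0, horizon_months = 36) {
  bad <- widths[horizon_months %% widths != 0]
  if (length(bad) > 0) {
    stop("widths must divide the horizon: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(widths = widths, minsup = minsup, models = models,
                 folds = folds, seed = seed,
                 horizon_months = horizon_months),
            class = "experiment_config")
}

## Assemble the integrated matrix for one width: mined timed features
## (IG-selected) joined with clinical and life-quality columns.
integrated_matrix <- function(cohort, db, patterns, width, config,
                              treatment = c("timed", "untimed"),
                              profiles = c("clinical", "treatment",
                                           "life_quality")) {
  treatment <- match.arg(treatment)
  labels <- cohort$patients$survived_3yr
  blocks <- list()
  selection_empty <- FALSE
  if ("treatment" %in% profiles) {
    if (treatment == "timed") {
      scheme <- bin_scheme(width, config$horizon_months)
      tm <- build_timed_matrix(db, patterns, scheme, labels)
      sel <- withCallingHandlers(
        select_by_ig(tm),
        warning = function(w) invokeRestart("muffleWarning"))
      selection_empty <- ncol(sel$features$x) == 0
      if (!selection_empty) blocks$treatment <- sel$features$x
    } else {
      blocks$treatment <- build_untimed_matrix(db, labels)$x
    }
  }
  if ("clinical" %in% profiles) blocks$clinical <- clinical_feature_matrix(cohort)
  if ("life_quality" %in% profiles) blocks$life_quality <- life_quality_matrix(cohort)
  if (length(blocks) == 0) stop("no profiles requested", call. = FALSE)
  x <- do.call(cbind, unname(blocks))
  list(features = new_feature_matrix(x, labels),
       selection_empty = selection_empty)
}

#' Interval-width sweep
#'
#' For each bin width: mine frequent substrings, build the timed matrix,
#' select by information gain, join with the clinical and life-quality
#' profiles, and cross-validate every model. One row per (width, model).
#'
#' @param cohort A cleaned `ov_cohort` with life quality attached.
#' @param config An [experiment_config()].
#' @return Data frame with width, model, accuracy, sensitivity, specificity,
#'   auc and a `note` column flagging widths whose feature selection came up
#'   empty (the run continues on the remaining profiles).
#' @export
run_interval_sweep <- function(cohort, config) {
  db <- build_sequence_db(cohort)
  patterns <- mine_frequent_substrings(db, config$minsup)
  rows <- list()
  for (w in config$widths) {
    im <- integrated_matrix(cohort, db, patterns, w, config, "timed")
    for (mn in names(config$models)) {
      cv <- cross_validate(im$features, config$models[[mn]],
                           k = config$folds, seed = config$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        width = w, model = mn, accuracy = cv$metrics$accuracy,
        sensitivity = cv$metrics$sensitivity,
        specificity = cv$metrics$specificity, auc = cv$metrics$auc,
        note = if (im$selection_empty) "empty treatment selection" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-profile ablation
#'
#' Cross-validates every model on each data profile alone (clinical,
#' timed-treatment at the given width, life quality) and reports all cells
#' plus the best model per profile (ties broken by AUC, then model name).
#'
#' @param cohort A cleaned `ov_cohort` with life quality attached.
#' @param config An [experiment_config()].
#' @param width Bin width for the treatment profile (default 2 months).
#' @return List with `table` (profile x model metrics) and `best` (one row
#'   per profile).
#' @export
run_profile_ablation <- function(cohort, config, width = 2) {
  db <- build_sequence_db(cohort)
  patterns <- mine_frequent_substrings(db, config$minsup)
  rows <- list()
  for (prof in c("clinical", "treatment", "life_quality")) {
    im <- integrated_matrix(cohort, db, patterns, width, config, "timed",
                            profiles = prof)
    for (mn in names(config$models)) {
      cv <- cross_validate(im$features, config$models[[mn]],
                           k = config$folds, seed = config$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        profile = prof, model = mn, accuracy = cv$metrics$accuracy,
        auc = cv$metrics$auc, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- do.call(rbind, lapply(split(tab, tab$profile), function(d) {
    d <- d[order(-d$accuracy, -d$auc, d$model), , drop = FALSE]
    d[1, , drop = FALSE]
  }))
  rownames(best) <- NULL
  list(table = tab, best = best)
}

#' Timed vs untimed (no-sequence-mining) comparison
#'
#' Runs the integrated pipeline with timed treatment features at each width
#' against the untimed treatment-presence baseline, on identical stratified
#' folds (assignment depends only on labels and the config seed, and is
#' asserted equal across arms). Each width's arms are compared by a paired
#' one-sided t-test over per-fold accuracies.
#'
#' @param cohort A cleaned `ov_cohort` with life quality attached.
#' @param config An [experiment_config()].
#' @param model_name Which model of `config$models` to compare with
#'   (default "boosting").
#' @return List with `table` (one row per width x arm) and `tests` (one
#'   paired t-test per width, timed vs untimed).
#' @export
run_sequence_ablation <- function(cohort, config, model_name = "boosting") {
  db <- build_sequence_db(cohort)
  patterns <- mine_frequent_substrings(db, config$minsup)
  spec <- config$models[[model_name]]
  labels <- cohort$patients$survived_3yr

  un <- integrated_matrix(cohort, db, patterns, config$widths[1], config,
                          "untimed")
  cv_un <- cross_validate(un$features, spec, k = config$folds,
                          seed = config$seed)
  rows <- list(data.frame(width = NA_real_, arm = "untimed",
                          accuracy = cv_un$metrics$accuracy,
                          sensitivity = cv_un$metrics$sensitivity,
                          specificity = cv_un$metrics$specificity,
                          auc = cv_un$metrics$auc, stringsAsFactors = FALSE))
  tests <- list()
  for (w in config$widths) {
    im <- integrated_matrix(cohort, db, patterns, w, config, "timed")
    cv_t <- cross_validate(im$features, spec, k = config$folds,
                           seed = config$seed)
    stopifnot(identical(cv_t$fold, cv_un$fold))   # shared folds across arms
    rows[[length(rows) + 1L]] <- data.frame(
      width = w, arm = "timed", accuracy = cv_t$metrics$accuracy,
      sensitivity = cv_t$metrics$sensitivity,
      specificity = cv_t$metrics$specificity, auc = cv_t$metrics$auc,
      stringsAsFactors = FALSE)
    tests[[as.character(w)]] <- tryCatch(
      paired_t_test(cv_t$fold_accuracy, cv_un$fold_accuracy),
      error = function(e) list(t = NA_real_, df = config$folds - 1,
                               p = NA_real_, significant = NA,
                               note = conditionMessage(e)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, tests = tests)
}

#' Paired t-test over per-fold accuracies
#'
#' One-sided by default: tests whether arm `a` outperforms arm `b` on the
#' shared folds, with df = k - 1.
#'
#' @param accuracies_a,accuracies_b Equal-length paired accuracy vectors.
#' @param alpha Significance level.
#' @param one_sided If TRUE, p is for "a > b"; otherwise two-sided.
#' @return List with `t`, `df`, `p`, `significant`.
#' @export
paired_t_test <- function(accuracies_a, accuracies_b, alpha = 0.05,
                          one_sided = TRUE) {
  if (length(accuracies_a) != length(accuracies_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  k <- length(accuracies_a)
  if (k < 2) stop("need at least 2 paired folds", call. = FALSE)
  d <- accuracies_a - accuracies_b
  s <- stats::sd(d)
  if (s == 0) {
    ## identical arms: no evidence either way (t = 0, one-sided p = 0.5);
    ## a constant nonzero difference leaves t undefined
    if (all(d == 0)) {
      return(list(t = 0, df = k - 1, p = if (one_sided) 0.5 else 1,
                  significant = FALSE))
    }
    stop("zero variance of paired differences; t statistic undefined",
         call. = FALSE)
  }
  t <- mean(d) / (s / sqrt(k))
  df <- k - 1
  p <- if (one_sided) stats::pt(t, df, lower.tail = FALSE) else
    2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, significant = p < alpha)
}
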