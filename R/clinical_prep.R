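## Clinical cleaning and class-conditional imputation.
##
## Cleaning mirrors standard practice for small retrospective cohorts:
## records without an outcome are unusable for supervised modelling, and
## records missing most of their clinical profile would dominate imputation
## error, so both are dropped before any imputation.

numeric_clinical_fields <- function() c("age", "ca125")
nominal_clinical_fields <- function() c("ascites", "grade", "stage", "histology")

#' Drop unusable patients
#'
#' Removes (1) patients with a missing 3-year survival label and (2) patients
#' with strictly more than 50% of the six clinical attribute fields missing
#' (age, CA-125, ascites, grade, stage, histology). Exactly 50% missing is
#' retained. Events of dropped patients are removed with them.
#'
#' @param cohort An `ov_cohort`.
#' @return List with the filtered `cohort` and a `report` counting drops.
#' @export
drop_unusable <- function(cohort) {
  p <- cohort$patients
  if (nrow(p) == 0) stop("cohort is empty", call. = FALSE)
  n_input <- nrow(p)

  miss_label <- is.na(p$survived_3yr)
  cf <- clinical_fields()
  miss_frac <- rowMeans(is.na(p[, cf, drop = FALSE]))
  high_miss <- !miss_label & miss_frac > 0.5

  keep <- !miss_label & !high_miss
  if (!any(keep)) {
    stop("all patients dropped: no usable records remain", call. = FALSE)
  }
  cohort$patients <- p[keep, , drop = FALSE]
  rownames(cohort$patients) <- NULL
  cohort$events <- cohort$events[
    cohort$events$patient_id %in% cohort$patients$patient_id, , drop = FALSE]
  rownames(cohort$events) <- NULL

  report <- list(n_input = n_input,
                 n_dropped_missing_label = sum(miss_label),
                 n_dropped_high_missing = sum(high_miss),
                 n_output = sum(keep))
  list(cohort = cohort, report = report)
}

class_mode <- function(x) {
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  ## deterministic tie-break: lexicographically smallest category
  list(value = sort(winners)[1], tie = length(winners) > 1)
}

#' Class-conditional mean/mode imputation
#'
#' Fills missing numeric clinical attributes (age, CA-125) with the mean over
#' same-survival-class patients, and missing nominal attributes (ascites,
#' grade, stage, histology) with the same-class mode. Mode ties are broken
#' deterministically by lexicographic order and recorded in the report. If a
#' field is missing for an entire class the overall mean/mode is used and the
#' fallback recorded. Observed cells are never altered.
#'
#' @param cohort An `ov_cohort` in which every patient has a survival label.
#' @return List with the imputed `cohort` and a `report` (cells imputed,
#'   per-class fill values, ties, fallbacks).
#' @export
impute_class_conditional <- function(cohort) {
  p <- cohort$patients
  if (any(is.na(p$survived_3yr))) {
    stop("impute_class_conditional requires every patient to have a survival ",
         "label; run drop_unusable() first", call. = FALSE)
  }
  classes <- sort(unique(p$survived_3yr))
  fill_values <- list()
  ties <- character(0)
  fallbacks <- character(0)
  n_imputed <- 0L

  impute_field <- function(field, numeric) {
    for (cl in classes) {
      in_cl <- p$survived_3yr == cl
      miss <- in_cl & is.na(p[[field]])
      if (!any(miss)) next
      obs <- p[[field]][in_cl & !is.na(p[[field]])]
      used_fallback <- length(obs) == 0
      if (used_fallback) obs <- p[[field]][!is.na(p[[field]])]
      if (length(obs) == 0) {
        stop(sprintf("field `%s` has no observed values at all", field),
             call. = FALSE)
      }
      if (numeric) {
        val <- mean(obs)
      } else {
        m <- class_mode(obs)
        ## grade is stored as integer but imputed as a nominal mode;
        ## keep the column's storage type
        val <- if (is.integer(p[[field]])) as.integer(m$value)
               else if (is.numeric(p[[field]])) as.numeric(m$value)
               else m$value
        if (m$tie) ties <<- c(ties, sprintf("%s/class=%s", field, cl))
      }
      if (used_fallback)
        fallbacks <<- c(fallbacks, sprintf("%s/class=%s", field, cl))
      p[[field]][miss] <<- val
      n_imputed <<- n_imputed + sum(miss)
      fill_values[[sprintf("%s/class=%s", field, cl)]] <<- val
    }
  }

  for (f in numeric_clinical_fields()) impute_field(f, numeric = TRUE)
  for (f in nominal_clinical_fields()) impute_field(f, numeric = FALSE)

  cohort$patients <- p
  report <- list(n_imputed_cells = n_imputed, fill_values = fill_values,
                 ties = ties, class_fallbacks = fallbacks)
  list(cohort = cohort, report = report)
}

#' Summarize a cleaned cohort
#'
#' Per-attribute ranges/medians and category counts, plus survival rate
#' (survivors / patients, in percent) by attribute group: categorical
#' attributes by level, age in decade bins, and — when present — ECOG level
#' and CCI score.
#'
#' @param cohort A cleaned `ov_cohort`.
#' @return List with `n`, `n_survivors`, `survival_rate_pct`, an
#'   `attributes` summary list, and `survival_by_group` (named list of data
#'   frames with columns group, n, survivors, survival_rate_pct).
#' @export
summarize_cohort <- function(cohort) {
  p <- cohort$patients
  y <- p$survived_3yr

  rate_by <- function(groups) {
    lv <- sort(unique(as.character(groups)))
    do.call(rbind, lapply(lv, function(g) {
      idx <- as.character(groups) == g
      data.frame(group = g, n = sum(idx), survivors = sum(y[idx]),
                 survival_rate_pct = round(100 * mean(y[idx]), 2),
                 stringsAsFactors = FALSE)
    }))
  }

  groups <- list(
    ascites = p$ascites,
    grade = p$grade,
    stage = p$stage,
    histology = p$histology,
    age_group = cut(p$age, breaks = seq(10, 90, by = 10), right = TRUE)
  )
  if (!is.null(p$ecog)) groups$ecog <- p$ecog
  if (!is.null(p$cci)) groups$cci <- p$cci

  list(
    n = nrow(p),
    n_survivors = sum(y),
    survival_rate_pct = round(100 * mean(y), 2),
    attributes = list(
      age = list(range = range(p$age), median = stats::median(p$age)),
      ca125 = list(range = range(p$ca125), median = stats::median(p$ca125)),
      ascites = table(p$ascites),
      grade = table(p$grade),
      stage = table(p$stage),
      histology = table(p$histology)
    ),
    survival_by_group = lapply(groups, rate_by)
  )
}
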