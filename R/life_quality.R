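#' Default Charlson Comorbidity Index weight table
#'
#' Classic Charlson weights for the conditions the pipeline recognises, with
#' two departures: end-organ-damage diabetes scores +3 (the weight used in
#' this study's scoring, versus the classic 2), and hypertension — recorded
#' in the cohort but carrying no classic Charlson weight — scores 0. Every
#' patient additionally receives a base malignancy weight of 2 for the index
#' cancer itself, which is why cohort CCI scores start at 2.
#'
#' @param base_malignancy_weight Weight added for the index malignancy
#'   (default 2); set to 0 to disable.
#' @return List with integer vector `weights` (code -> weight) and
#'   `base_malignancy_weight`.
#' @export
default_cci_weights <- function(base_malignancy_weight = 2L) {
  list(
    weights = c(mi = 1L, chf = 1L, pvd = 1L, cvd = 1L, dementia = 1L,
                copd = 1L, connective_tissue = 1L, ulcer = 1L,
                mild_liver = 1L, diabetes_uncomplicated = 1L,
                hemiplegia = 2L, renal = 2L, diabetes_end_organ = 3L,
                hypertension = 0L),
    base_malignancy_weight = as.integer(base_malignancy_weight)
  )
}

#' Charlson Comorbidity Index for one patient
#'
#' Sums the configured weights over the patient's comorbidity flags.
#' Uncomplicated and end-organ-damage diabetes are mutually exclusive: when
#' both flags are present only the severer (+3) is counted. When the base
#' malignancy weight is enabled it is added for every patient.
#'
#' @param flags Character vector of comorbidity codes present (may be empty).
#' @param weights Weight table from [default_cci_weights()].
#' @return Integer CCI score.
#' @export
compute_cci <- function(flags, weights = default_cci_weights()) {
  flags <- unique(as.character(flags))
  unknown <- setdiff(flags, names(weights$weights))
  if (length(unknown) > 0) {
    stop(sprintf("unknown comorbidity code(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(weights$weights), collapse = ", ")),
         call. = FALSE)
  }
  if (all(c("diabetes_uncomplicated", "diabetes_end_organ") %in% flags)) {
    flags <- setdiff(flags, "diabetes_uncomplicated")
  }
  as.integer(weights$base_malignancy_weight +
               sum(weights$weights[flags]))
}

#' Attach quality-of-life columns (CCI and ECOG) to a cohort
#'
#' Computes each patient's Charlson Comorbidity Index from the `com_*` flag
#' columns and validates ECOG performance status (integer 1--5). CCI and
#' ECOG together form the life-quality profile of the integrated dataset.
#'
#' @param cohort An `ov_cohort`.
#' @param weights Weight table from [default_cci_weights()].
#' @return The cohort with an integer `cci` column added.
#' @export
attach_life_quality <- function(cohort, weights = default_cci_weights()) {
  p <- cohort$patients
  flag_cols <- grep("^com_", names(p), value = TRUE)
  codes <- sub("^com_", "", flag_cols)
  if (any(!p$ecog %in% 1:5)) {
    stop("ecog values must be integers in 1..5", call. = FALSE)
  }
  p$cci <- vapply(seq_len(nrow(p)), function(i) {
    compute_cci(codes[as.logical(p[i, flag_cols])], weights)
  }, integer(1))
  cohort$patients <- p
  cohort
}
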