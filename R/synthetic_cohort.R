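## Treatment alphabet used throughout: multiple lines of therapy recorded for
## advanced ovarian cancer (primary/interval debulking surgery, chemotherapy,
## neoadjuvant chemotherapy, cytoreductive surgery, hormonal therapy).

#' Default treatment alphabet
#'
#' The five treatment modalities recorded per line of therapy for advanced
#' ovarian cancer patients.
#'
#' @return Character vector of treatment symbols.
#' @export
ov_treatments <- function() {
  c("Surgery", "Chemotherapy", "NACT", "CRS", "HormonalTherapy")
}

## Clinical attribute columns subject to missingness / imputation.
clinical_fields <- function() {
  c("age", "ca125", "ascites", "grade", "stage", "histology")
}

#' Default marginal distributions for clinical attributes
#'
#' Ranges and category frequencies mirror a typical advanced ovarian cancer
#' cohort: age 17--80 (median ~54), CA-125 8.7--16301 U/ml (median ~929,
#' lognormal), ascites present in ~80%, grade 2--4 (median 3), FIGO substage
#' 3a--4 (most patients 3c/4), histology dominated by serous carcinoma,
#' ECOG performance status 1--5 (median 2).
#'
#' @return Named list of per-attribute distribution parameters.
#' @export
default_clinical_distributions <- function() {
  list(
    age = list(range = c(17, 80), mean = 54, sd = 12, unif_mix = 0.3),
    ca125 = list(range = c(8.7, 16301), meanlog = log(929.13), sdlog = 1.2),
    ascites = list(p_yes = 114 / 140),
    grade = list(levels = c(2L, 3L, 4L), probs = c(0.15, 0.60, 0.25)),
    stage = list(levels = c("3a", "3b", "3c", "4"),
                 probs = c(0.05, 0.10, 0.30, 0.55)),
    histology = list(
      levels = c("serous", "poorly_differentiated", "mucinous",
                 "endometrioid", "mixed", "clear_cell", "small_cell",
                 "germ_cell"),
      probs = c(111, 13, 6, 4, 3, 1, 1, 1) / 140),
    ecog = list(levels = 1:5, probs = c(0.30, 0.35, 0.20, 0.10, 0.05)),
    comorbidity_rates = c(copd = 0.10, diabetes_uncomplicated = 0.20,
                          diabetes_end_organ = 0.05, hypertension = 0.30,
                          mi = 0.05, chf = 0.05, renal = 0.05)
  )
}

#' Default first-order treatment-transition grammar
#'
#' Initial-state and transition probabilities over the treatment alphabet.
#' The grammar places non-trivial mass on the seven transition pairs commonly
#' observed in advanced ovarian cancer treatment lines (surgery followed by
#' chemotherapy, NACT followed by surgery, chemotherapy followed by CRS, ...).
#'
#' @return List with `initial` (named probability vector), `transition`
#'   (row-stochastic matrix), `n_lines_probs` (probabilities for 1..max_lines
#'   treatment lines), and `gap` (lognormal inter-treatment gap parameters in
#'   months).
#' @export
default_treatment_grammar <- function() {
  ab <- ov_treatments()
  tr <- matrix(0, 5, 5, dimnames = list(ab, ab))
  tr["Surgery", ] <- c(0.05, 0.55, 0.15, 0.05, 0.20)
  tr["Chemotherapy", ] <- c(0.15, 0.15, 0.00, 0.40, 0.30)
  tr["NACT", ] <- c(0.50, 0.25, 0.00, 0.05, 0.20)
  tr["CRS", ] <- c(0.10, 0.60, 0.00, 0.00, 0.30)
  tr["HormonalTherapy", ] <- c(0.30, 0.50, 0.00, 0.00, 0.20)
  list(
    initial = c(Surgery = 0.35, Chemotherapy = 0.30, NACT = 0.30,
                CRS = 0.025, HormonalTherapy = 0.025),
    transition = tr,
    n_lines_probs = c(0.12, 0.38, 0.32, 0.18),
    ## most next-line treatments arrive within 6--8 months of the previous one
    gap = list(meanlog = log(6), sdlog = 0.6)
  )
}

#' Default planted timed-transition effect
#'
#' A survival effect attached to patients whose sequence contains CRS
#' immediately after chemotherapy with an inter-treatment gap in (2, 6]
#' months. The gap window makes the effect visible to time-binned transition
#' features but invisible to treatment-presence (untimed) features.
#'
#' @param weight Log-odds contribution to 3-year survival (default 2).
#' @return List with fields `source`, `target`, `gap_range`, `weight`.
#' @export
default_planted_pattern <- function(weight = 2) {
  list(source = "Chemotherapy", target = "CRS",
       gap_range = c(2, 6), weight = weight)
}

#' Specify a synthetic cohort
#'
#' Bundles every knob of the generator: cohort size, target 3-year survival
#' prevalence, the treatment grammar, clinical marginals, signed log-odds
#' effects of (standardized) attributes on survival, an optional planted
#' timed-transition effect, and missingness rates.
#'
#' @param n_patients Number of patients (>= 10).
#' @param survival_prevalence Target fraction surviving 3 years, in (0,1).
#' @param horizon_months Follow-up horizon in months.
#' @param treatment_alphabet Treatment symbols.
#' @param max_lines Maximum number of treatment lines per patient.
#' @param clinical_distributions See [default_clinical_distributions()].
#' @param grammar See [default_treatment_grammar()].
#' @param effect_coefficients Named numeric vector of log-odds weights per
#'   standardized attribute; supported names are `age`, `ca125`, `grade`,
#'   `ecog`, `cci`, `ascites`.
#' @param planted_pattern Optional list as from [default_planted_pattern()].
#' @param missing_rate MCAR masking probability per clinical cell, in [0,1).
#' @param label_missing_rate Fraction of patients whose survival label is
#'   masked, in [0,1).
#' @param seed Integer root seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 140,
                        survival_prevalence = 0.4214,
                        horizon_months = 36,
                        treatment_alphabet = ov_treatments(),
                        max_lines = 4,
                        clinical_distributions = default_clinical_distributions(),
                        grammar = default_treatment_grammar(),
                        effect_coefficients = c(age = -0.4, ecog = -0.8,
                                                cci = -0.5),
                        planted_pattern = NULL,
                        missing_rate = 0,
                        label_missing_rate = 0,
                        seed = 1) {
  spec <- list(n_patients = n_patients,
               survival_prevalence = survival_prevalence,
               horizon_months = horizon_months,
               treatment_alphabet = treatment_alphabet,
               max_lines = max_lines,
               clinical_distributions = clinical_distributions,
               grammar = grammar,
               effect_coefficients = effect_coefficients,
               planted_pattern = planted_pattern,
               missing_rate = missing_rate,
               label_missing_rate = label_missing_rate,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort_spec field `%s`: %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(spec$n_patients) || spec$n_patients < 10)
    stop_field("n_patients", "must be >= 10")
  if (spec$survival_prevalence <= 0 || spec$survival_prevalence >= 1)
    stop_field("survival_prevalence", "must lie in (0, 1)")
  if (spec$horizon_months < 1)
    stop_field("horizon_months", "must be >= 1")
  if (spec$max_lines < 1)
    stop_field("max_lines", "must be >= 1")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop_field("missing_rate", "must lie in [0, 1)")
  if (spec$label_missing_rate < 0 || spec$label_missing_rate >= 1)
    stop_field("label_missing_rate", "must lie in [0, 1)")
  pp <- spec$planted_pattern
  if (!is.null(pp)) {
    if (!all(c(pp$source, pp$target) %in% spec$treatment_alphabet))
      stop_field("planted_pattern",
                 "source/target symbols must belong to treatment_alphabet")
    if (length(pp$gap_range) != 2 || pp$gap_range[1] >= pp$gap_range[2])
      stop_field("planted_pattern", "gap_range must be an increasing pair")
  }
  invisible(spec)
}

## Deterministic sub-stream seeds below 2^31, split off a root seed so that
## patients, labels and missingness each draw from independent streams.
derive_seed <- function(seed, stream, i = 0L) {
  offset <- c(patient = 11L, label = 29L, missing = 47L)[[stream]]
  as.integer((as.double(seed) * 7919 + offset * 104729 + i * 131) %% 2147483647)
}

sample_one <- function(levels, probs) {
  levels[sample.int(length(levels), 1L, prob = probs)]
}

generate_patient <- function(spec, i) {
  set.seed(derive_seed(spec$seed, "patient", i))
  cd <- spec$clinical_distributions
  g <- spec$grammar

  age <- if (stats::runif(1) < cd$age$unif_mix) {
    stats::runif(1, cd$age$range[1], cd$age$range[2])
  } else {
    min(max(stats::rnorm(1, cd$age$mean, cd$age$sd), cd$age$range[1]),
        cd$age$range[2])
  }
  ca125 <- min(max(stats::rlnorm(1, cd$ca125$meanlog, cd$ca125$sdlog),
                   cd$ca125$range[1]), cd$ca125$range[2])
  flags <- stats::runif(length(cd$comorbidity_rates)) < cd$comorbidity_rates
  names(flags) <- names(cd$comorbidity_rates)

  n_lines <- sample.int(spec$max_lines, 1L,
                        prob = g$n_lines_probs[seq_len(spec$max_lines)])
  symbols <- character(0)
  offsets <- numeric(0)
  t <- stats::runif(1, 0, 2)   # diagnosis to first treatment
  cur <- sample_one(names(g$initial), g$initial)
  for (l in seq_len(n_lines)) {
    if (t > spec$horizon_months) break
    symbols <- c(symbols, cur)
    offsets <- c(offsets, t)
    if (l == n_lines) break
    gap <- stats::rlnorm(1, g$gap$meanlog, g$gap$sdlog)
    t <- t + gap
    cur <- sample_one(colnames(g$transition), g$transition[cur, ])
  }

  list(
    patient = data.frame(
      patient_id = sprintf("P%04d", i),
      age = round(age, 1),
      ca125 = round(ca125, 2),
      ascites = if (stats::runif(1) < cd$ascites$p_yes) "yes" else "no",
      grade = sample_one(cd$grade$levels, cd$grade$probs),
      stage = sample_one(cd$stage$levels, cd$stage$probs),
      histology = sample_one(cd$histology$levels, cd$histology$probs),
      ecog = sample_one(cd$ecog$levels, cd$ecog$probs),
      stringsAsFactors = FALSE),
    flags = flags,
    symbols = symbols,
    offsets = round(offsets, 3)
  )
}

## Does a sequence contain target immediately after source with gap in
## (lo, hi] months?  Mirrors the half-open binning convention.
has_timed_transition <- function(symbols, offsets, pp) {
  if (length(symbols) < 2) return(FALSE)
  for (j in seq_len(length(symbols) - 1L)) {
    if (symbols[j] == pp$source && symbols[j + 1L] == pp$target) {
      gap <- offsets[j + 1L] - offsets[j]
      if (gap > pp$gap_range[1] && gap <= pp$gap_range[2]) return(TRUE)
    }
  }
  FALSE
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic advanced ovarian cancer cohort
#'
#' Draws clinical attributes, comorbidity flags, ECOG status and multi-line
#' treatment sequences per patient, then assigns 3-year survival labels from
#' a logistic model: the linear predictor sums signed effects of standardized
#' attributes (CCI is computed from the drawn comorbidity flags) plus the
#' planted timed-transition indicator, and the intercept is calibrated by
#' bisection so the mean survival probability matches the target prevalence
#' to within 0.02.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `ov_cohort`: list with `patients` (one row per
#'   patient) and `events` (long-format treatment log with `patient_id`,
#'   `treatment`, `month_offset`).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_patients
  drawn <- lapply(seq_len(n), function(i) generate_patient(spec, i))

  patients <- do.call(rbind, lapply(drawn, `[[`, "patient"))
  flags <- do.call(rbind, lapply(drawn, `[[`, "flags"))
  colnames(flags) <- paste0("com_", colnames(flags))
  patients <- cbind(patients, as.data.frame(flags))

  events <- do.call(rbind, lapply(drawn, function(d) {
    if (length(d$symbols) == 0) return(NULL)
    data.frame(patient_id = d$patient$patient_id, treatment = d$symbols,
               month_offset = d$offsets, stringsAsFactors = FALSE)
  }))
  if (is.null(events)) {
    events <- data.frame(patient_id = character(0), treatment = character(0),
                         month_offset = numeric(0))
  }
  rownames(events) <- NULL

  ## linear predictor from standardized attributes + planted indicator
  cci <- vapply(drawn, function(d) {
    compute_cci(names(which(d$flags)), default_cci_weights())
  }, integer(1))
  covars <- list(
    age = standardize(patients$age),
    ca125 = standardize(log(patients$ca125)),
    grade = standardize(as.numeric(patients$grade)),
    ecog = standardize(patients$ecog),
    cci = standardize(cci),
    ascites = as.numeric(patients$ascites == "yes") -
      mean(patients$ascites == "yes")
  )
  eta <- rep(0, n)
  for (nm in names(spec$effect_coefficients)) {
    if (!nm %in% names(covars))
      stop(sprintf("unknown effect_coefficients name `%s`", nm), call. = FALSE)
    eta <- eta + spec$effect_coefficients[[nm]] * covars[[nm]]
  }
  if (!is.null(spec$planted_pattern)) {
    carrier <- vapply(drawn, function(d) {
      has_timed_transition(d$symbols, d$offsets, spec$planted_pattern)
    }, logical(1))
    eta <- eta + spec$planted_pattern$weight * as.numeric(carrier)
  }

  ## bisection on the intercept so mean survival prob hits the prevalence
  target <- spec$survival_prevalence
  lo <- -12; hi <- 12
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mean(stats::plogis(mid + eta)) < target) lo <- mid else hi <- mid
  }
  p <- stats::plogis((lo + hi) / 2 + eta)

  set.seed(derive_seed(spec$seed, "label"))
  patients$survived_3yr <- as.integer(stats::runif(n) < p)
  rownames(patients) <- NULL

  structure(list(patients = patients, events = events,
                 alphabet = spec$treatment_alphabet,
                 horizon_months = spec$horizon_months),
            class = "ov_cohort")
}

#' @export
print.ov_cohort <- function(x, ...) {
  cat(sprintf("ov_cohort: %d patients, %d treatment events", nrow(x$patients),
              nrow(x$events)))
  if (!all(is.na(x$patients$survived_3yr))) {
    cat(sprintf(", 3-yr survival %.1f%%",
                100 * mean(x$patients$survived_3yr, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Mask clinical cells (and optionally labels) completely at random
#'
#' Each of the six clinical attribute cells (age, CA-125, ascites, grade,
#' stage, histology) is masked independently with probability
#' `spec$missing_rate`; survival labels are masked for a fraction
#' `spec$label_missing_rate` of patients. Treatment events are never masked.
#'
#' @param cohort An `ov_cohort`.
#' @param spec The [cohort_spec()] carrying the rates and seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, spec) {
  validate_cohort_spec(spec)
  p <- cohort$patients
  n <- nrow(p)
  set.seed(derive_seed(spec$seed, "missing"))
  for (f in clinical_fields()) {
    mask <- stats::runif(n) < spec$missing_rate
    p[[f]][mask] <- NA
  }
  if (spec$label_missing_rate > 0) {
    mask <- stats::runif(n) < spec$label_missing_rate
    p$survived_3yr[mask] <- NA
  }
  cohort$patients <- p
  cohort
}

#' Write / read a cohort as two CSV files
#'
#' `write_cohort()` writes `patients.csv` (one row per patient) and
#' `events.csv` (long-format treatment log). `read_cohort()` reads them back,
#' validating treatment symbols, non-negative month offsets and per-patient
#' chronological ordering; violations raise a parse error naming the row.
#'
#' @param cohort An `ov_cohort`.
#' @param dir Directory for the two CSV files.
#' @param alphabet Allowed treatment symbols on read.
#' @return `read_cohort()` returns an `ov_cohort`; `write_cohort()` the paths,
#'   invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  ep <- file.path(dir, "events.csv")
  utils::write.csv(cohort$patients, pp, row.names = FALSE, na = "")
  utils::write.csv(cohort$events, ep, row.names = FALSE, na = "")
  invisible(c(patients = pp, events = ep))
}

#' @rdname write_cohort
#' @param horizon_months Follow-up horizon recorded on the cohort.
#' @export
read_cohort <- function(dir, alphabet = ov_treatments(),
                        horizon_months = 36) {
  pp <- file.path(dir, "patients.csv")
  ep <- file.path(dir, "events.csv")
  if (!file.exists(pp) || !file.exists(ep))
    stop("expected patients.csv and events.csv under ", dir, call. = FALSE)
  patients <- utils::read.csv(pp, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"),
                              na.strings = "")
  patients$stage <- as.character(patients$stage)
  events <- utils::read.csv(ep, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character"),
                            na.strings = "")
  bad <- which(!events$treatment %in% alphabet)
  if (length(bad) > 0)
    stop(sprintf("events.csv row %d: unknown treatment symbol `%s`",
                 bad[1], events$treatment[bad[1]]), call. = FALSE)
  bad <- which(events$month_offset < 0)
  if (length(bad) > 0)
    stop(sprintf("events.csv row %d: negative month_offset", bad[1]),
         call. = FALSE)
  off_prev <- c(-Inf, events$month_offset[-nrow(events)])
  same_pat <- c(FALSE, events$patient_id[-1] == events$patient_id[-nrow(events)])
  bad <- which(same_pat & events$month_offset < off_prev)
  if (length(bad) > 0)
    stop(sprintf("events.csv row %d: month_offset out of order", bad[1]),
         call. = FALSE)
  structure(list(patients = patients, events = events, alphabet = alphabet,
                 horizon_months = horizon_months),
            class = "ov_cohort")
}
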