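# In-code fixtures shared across test files.

# Hand-built cohort from a patients data frame and an optional event log.
make_cohort <- function(patients, events = NULL, alphabet = ov_treatments(),
                        horizon = 36) {
  if (is.null(events)) {
    events <- data.frame(patient_id = character(0), treatment = character(0),
                         month_offset = numeric(0))
  }
  structure(list(patients = patients, events = events, alphabet = alphabet,
                 horizon_months = horizon),
            class = "ov_cohort")
}

# Minimal patients table; clinical fields default to complete values.
make_patients <- function(n, survived = rep(1L, n)) {
  data.frame(patient_id = sprintf("P%04d", seq_len(n)),
             age = rep(55, n), ca125 = rep(900, n),
             ascites = rep("yes", n), grade = rep(3L, n),
             stage = rep("3c", n), histology = rep("serous", n),
             ecog = rep(2L, n), survived_3yr = survived,
             stringsAsFactors = FALSE)
}

# Sequence database straight from symbol lists (offsets default to months
# 0, 6, 12, ...).
make_db <- function(seqs, alphabet = NULL, offsets = NULL) {
  ids <- sprintf("P%04d", seq_along(seqs))
  names(seqs) <- ids
  if (is.null(offsets)) {
    offsets <- lapply(seqs, function(s) if (length(s)) 6 * (seq_along(s) - 1)
                      else numeric(0))
  } else {
    names(offsets) <- ids
  }
  if (is.null(alphabet)) alphabet <- sort(unique(c(unlist(seqs), "Z0")))
  structure(list(patient_ids = ids, symbols = seqs, offsets = offsets,
                 alphabet = alphabet, n = length(seqs)),
            class = "ov_seqdb")
}

# Random sequence database for fuzzing the miner against the oracle.
random_db <- function(n_seq, alphabet, max_len, allow_empty = TRUE) {
  seqs <- lapply(seq_len(n_seq), function(i) {
    len <- sample.int(max_len + as.integer(allow_empty), 1) -
      as.integer(allow_empty)
    if (len <= 0) character(0) else sample(alphabet, len, replace = TRUE)
  })
  make_db(seqs, alphabet = alphabet)
}

# Independent information-gain oracle: contingency-table arithmetic with an
# explicit x*log2(x) kernel, no shared code with the implementation.
ig_oracle <- function(feature, labels) {
  xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)
  n <- length(labels)
  tab <- table(feature, labels)
  h_total <- -sum(xlog2(colSums(tab) / n))
  h_cond <- 0
  for (r in seq_len(nrow(tab))) {
    nr <- sum(tab[r, ])
    h_cond <- h_cond + (nr / n) * (-sum(xlog2(tab[r, ] / nr)))
  }
  h_total - h_cond
}

# Pattern tables as canonical key sets, for set comparison.
pattern_keys <- function(patterns) {
  sort(paste(patterns$pattern, patterns$support_count, sep = "@"))
}
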