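## Frequent contiguous (no-gap) treatment-substring mining.
##
## The miner is a level-wise GSP variant adjusted to count *substrings*: a
## pattern matches a patient only when its symbols occur consecutively in the
## patient's treatment line — an intervening therapy W between X and Y
## disqualifies X -> Y for that occurrence. Support is counted once per
## patient (set semantics), and a pattern is frequent when its support count
## reaches ceiling(minsup * |DB|), the "at least" reading of relative support.

#' Build a per-patient treatment-sequence database
#'
#' One entry per patient in the cohort (patients without any recorded
#' treatment are kept with empty sequences — they still count toward the
#' database size used for relative support). Events are stably sorted by
#' month offset within patient.
#'
#' @param cohort An `ov_cohort`.
#' @return Object of class `ov_seqdb`: `patient_ids`, parallel lists
#'   `symbols` and `offsets`, `alphabet`, and size `n`.
#' @export
build_sequence_db <- function(cohort) {
  ids <- cohort$patients$patient_id
  ev <- cohort$events
  symbols <- stats::setNames(vector("list", length(ids)), ids)
  offsets <- symbols
  for (id in ids) {
    rows <- ev[ev$patient_id == id, , drop = FALSE]
    ord <- order(rows$month_offset)   # stable in R
    symbols[[id]] <- rows$treatment[ord]
    offsets[[id]] <- rows$month_offset[ord]
  }
  structure(list(patient_ids = ids, symbols = symbols, offsets = offsets,
                 alphabet = cohort$alphabet, n = length(ids)),
            class = "ov_seqdb")
}

contains_run <- function(seq, pattern) {
  k <- length(pattern)
  m <- length(seq)
  if (m < k) return(FALSE)
  for (s in seq_len(m - k + 1L)) {
    if (all(seq[s:(s + k - 1L)] == pattern)) return(TRUE)
  }
  FALSE
}

#' Patient-level support of a contiguous pattern
#'
#' Counts patients whose treatment sequence contains `symbols` as a
#' contiguous run; a patient counts at most once however many occurrences
#' her sequence holds.
#'
#' @param db An `ov_seqdb`.
#' @param symbols Non-empty character vector of treatment symbols.
#' @return Integer support count.
#' @export
substring_support <- function(db, symbols) {
  if (length(symbols) == 0) stop("pattern must be non-empty", call. = FALSE)
  sum(vapply(db$symbols, contains_run, logical(1), pattern = symbols))
}

## ceiling(minsup * n) guarded against floating-point up-rounding
## (0.05 * 140 is 7 + 4e-16 in double arithmetic).
min_support_count <- function(minsup, n) {
  as.integer(ceiling(minsup * n - 1e-9))
}

pattern_frame <- function(keys, counts, n) {
  syms <- strsplit(keys, "\u001f", fixed = TRUE)
  lens <- lengths(syms)
  df <- data.frame(pattern = vapply(syms, paste, "", collapse = "->"),
                   length = lens, support_count = as.integer(counts),
                   relative_support = counts / n, stringsAsFactors = FALSE)
  df$symbols <- syms
  ord <- order(df$length, -df$support_count, df$pattern, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Mine frequent contiguous treatment substrings (modified GSP)
#'
#' Level-wise mining: frequent single symbols form L1; length-(k+1)
#' candidates join frequent k-patterns whose length-(k-1) suffix/prefix
#' agree; candidates with an infrequent contiguous sub-pattern are pruned;
#' support is counted per patient with the no-gap constraint. Patterns with
#' relative support of at least `minsup` are returned, ordered by length,
#' then support descending, then lexicographically.
#'
#' @param db An `ov_seqdb`.
#' @param minsup Relative support threshold in (0, 1].
#' @param max_len Optional cap on pattern length.
#' @return Data frame with columns `pattern` (symbols joined by `->`),
#'   `length`, `support_count`, `relative_support`, and list column
#'   `symbols`.
#' @export
mine_frequent_substrings <- function(db, minsup, max_len = NULL) {
  if (!is.numeric(minsup) || minsup <= 0 || minsup > 1) {
    stop("minsup must lie in (0, 1]", call. = FALSE)
  }
  if (db$n == 0) stop("sequence database is empty", call. = FALSE)
  thr <- min_support_count(minsup, db$n)
  if (is.null(max_len)) {
    max_len <- max(c(0L, lengths(db$symbols)))
  }
  sep <- "\u001f"
  keys <- character(0)
  counts <- integer(0)

  level <- lapply(sort(db$alphabet), identity)     # length-1 candidates
  k <- 1L
  while (length(level) > 0 && k <= max_len) {
    sup <- vapply(level, function(pat) substring_support(db, pat), integer(1))
    freq <- level[sup >= thr]
    if (length(freq) > 0) {
      keys <- c(keys, vapply(freq, paste, "", collapse = sep))
      counts <- c(counts, sup[sup >= thr])
    }
    if (length(freq) == 0 || k == max_len) break
    ## join step: suffix of a equals prefix of b -> candidate c(a, last(b))
    freq_keys <- vapply(freq, paste, "", collapse = sep)
    cand <- list()
    for (a in freq) {
      a_suffix <- if (k == 1L) character(0) else a[-1L]
      for (b in freq) {
        b_prefix <- if (k == 1L) character(0) else b[-k]
        if (identical(a_suffix, b_prefix)) {
          cand[[length(cand) + 1L]] <- c(a, b[k])
        }
      }
    }
    ## prune: every contiguous length-k sub-pattern must be frequent
    cand <- Filter(function(pat) {
      subs <- lapply(1:2, function(s) pat[s:(s + k - 1L)])
      all(vapply(subs, paste, "", collapse = sep) %in% freq_keys)
    }, cand)
    level <- cand
    k <- k + 1L
  }
  pattern_frame(keys, counts, db$n)
}

#' Brute-force frequent-substring oracle
#'
#' Independent reference for [mine_frequent_substrings()]: each patient's
#' distinct contiguous substrings (up to `max_len`) are enumerated directly
#' and tallied across patients; patterns reaching `minsup` relative support
#' are returned in the same order and shape as the miner. Guarded to at most
#' 1e6 enumerated candidates.
#'
#' @inheritParams mine_frequent_substrings
#' @return Data frame as from [mine_frequent_substrings()].
#' @export
brute_force_frequent <- function(db, minsup, max_len = NULL) {
  if (!is.numeric(minsup) || minsup <= 0 || minsup > 1) {
    stop("minsup must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(max_len)) max_len <- max(c(0L, lengths(db$symbols)))
  if (max_len >= 1 && length(db$alphabet)^min(max_len, 10) > 1e6) {
    stop("candidate space exceeds 1e6; lower max_len", call. = FALSE)
  }
  sep <- "\u001f"
  tally <- new.env(parent = emptyenv())
  for (seq in db$symbols) {
    m <- length(seq)
    if (m == 0) next
    seen <- character(0)
    for (s in seq_len(m)) {
      for (e in s:min(m, s + max_len - 1L)) {
        seen <- c(seen, paste(seq[s:e], collapse = sep))
      }
    }
    for (key in unique(seen)) {
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    }
  }
  keys <- ls(tally)
  counts <- vapply(keys, function(k) tally[[k]], integer(1))
  keep <- counts / db$n >= minsup - 1e-12
  pattern_frame(keys[keep], counts[keep], db$n)
}
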