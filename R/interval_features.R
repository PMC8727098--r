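## Time-binned treatment-transition features and information-gain selection.
##
## A frequent transition (X, Y) generates one binary column per time bin:
## "X_Tk_Y" fires for a patient when Y immediately follows X (no intervening
## therapy) with an inter-treatment gap in bin k. Bins are half-open
## ((k-1)*w, k*w], with a gap of exactly 0 assigned to T_1, so "within one
## month" lands in T_1 at width 1.

#' Time-bin scheme
#'
#' @param width_months Bin width in months (integer 1--6, must divide the
#'   horizon).
#' @param horizon_months Follow-up horizon in months (default 36).
#' @return Object of class `bin_scheme` with `width_months`,
#'   `horizon_months`, `n_bins`.
#' @export
bin_scheme <- function(width_months, horizon_months = 36) {
  if (width_months < 1 || width_months != round(width_months)) {
    stop("width_months must be a positive integer", call. = FALSE)
  }
  if (horizon_months %% width_months != 0) {
    stop("width_months must divide horizon_months", call. = FALSE)
  }
  structure(list(width_months = as.integer(width_months),
                 horizon_months = as.integer(horizon_months),
                 n_bins = as.integer(horizon_months / width_months)),
            class = "bin_scheme")
}

#' Map an inter-treatment gap to its time bin
#'
#' `k = ceiling(gap / width)`, with gap 0 mapped to bin 1 (treatments
#' starting together count as "within the first interval") and gaps beyond
#' the horizon mapped to `NA` (no feature fires).
#'
#' @param gap_months Non-negative gap in months (vectorized).
#' @param scheme A [bin_scheme()].
#' @return Integer bin indices, `NA` for out-of-horizon gaps.
#' @export
bin_index <- function(gap_months, scheme) {
  if (any(gap_months < 0)) stop("gap_months must be >= 0", call. = FALSE)
  k <- pmax(1L, as.integer(ceiling(gap_months / scheme$width_months)))
  k[gap_months > scheme$horizon_months] <- NA_integer_
  k
}

new_feature_matrix <- function(x, labels = NULL) {
  structure(list(x = x, patient_ids = rownames(x),
                 feature_names = colnames(x), labels = labels),
            class = "ov_features")
}

#' @export
print.ov_features <- function(x, ...) {
  cat(sprintf("ov_features: %d patients x %d binary features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

#' Timed transition feature matrix
#'
#' For every frequent length-2 pattern (X, Y) and every time bin T_k, the
#' column `X_Tk_Y` is 1 for patients with at least one adjacent X -> Y
#' occurrence whose gap falls in bin k (multiple occurrences with different
#' gaps set multiple bin columns). All-zero columns are dropped; column
#' order is deterministic (pattern order, then k ascending).
#'
#' @param db An `ov_seqdb`.
#' @param patterns Data frame from [mine_frequent_substrings()]; only its
#'   length-2 rows generate columns.
#' @param scheme A [bin_scheme()].
#' @param labels Optional binary label vector aligned with the database's
#'   patients.
#' @return An `ov_features` object.
#' @export
build_timed_matrix <- function(db, patterns, scheme, labels = NULL) {
  pairs <- patterns[patterns$length == 2, , drop = FALSE]
  all_syms <- unique(unlist(pairs$symbols))
  if (length(all_syms) > 0 && !all(all_syms %in% db$alphabet)) {
    stop("pattern symbols outside the database alphabet", call. = FALSE)
  }
  n <- db$n
  cols <- list()
  for (r in seq_len(nrow(pairs))) {
    xy <- pairs$symbols[[r]]
    block <- matrix(0L, nrow = n, ncol = scheme$n_bins,
                    dimnames = list(db$patient_ids,
                                    sprintf("%s_T%d_%s", xy[1],
                                            seq_len(scheme$n_bins), xy[2])))
    for (i in seq_len(n)) {
      sym <- db$symbols[[i]]
      off <- db$offsets[[i]]
      if (length(sym) < 2) next
      for (j in seq_len(length(sym) - 1L)) {
        if (sym[j] == xy[1] && sym[j + 1L] == xy[2]) {
          k <- bin_index(off[j + 1L] - off[j], scheme)
          if (!is.na(k)) block[i, k] <- 1L
        }
      }
    }
    cols[[length(cols) + 1L]] <- block
  }
  x <- if (length(cols) > 0) do.call(cbind, cols) else
    matrix(0L, nrow = n, ncol = 0, dimnames = list(db$patient_ids, NULL))
  x <- x[, colSums(x) > 0, drop = FALSE]
  new_feature_matrix(x, labels)
}

#' Untimed treatment-presence matrix
#'
#' One column per treatment symbol in the alphabet; a cell is 1 when the
#' patient ever received that treatment, irrespective of order or timing.
#' This is the no-sequence-mining baseline encoding.
#'
#' @param db An `ov_seqdb`.
#' @param labels Optional aligned binary label vector.
#' @return An `ov_features` object.
#' @export
build_untimed_matrix <- function(db, labels = NULL) {
  ab <- db$alphabet
  x <- matrix(0L, nrow = db$n, ncol = length(ab),
              dimnames = list(db$patient_ids, ab))
  for (i in seq_len(db$n)) {
    x[i, intersect(unique(db$symbols[[i]]), ab)] <- 1L
  }
  new_feature_matrix(x, labels)
}

#' Shannon entropy of a label vector, in bits
#'
#' `Info(D) = -sum_i p_i log2 p_i` over class proportions, with
#' `0 * log2(0)` taken as 0.
#'
#' @param labels Non-empty discrete vector.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a binary feature for binary labels
#'
#' `Gain(A) = Info(D) - Info_A(D)` where `Info_A(D)` is the
#' proportion-weighted entropy of the label within each feature value.
#'
#' @param feature Binary feature column.
#' @param labels Binary labels, same length.
#' @return Gain in bits (non-negative up to rounding).
#' @export
info_gain <- function(feature, labels) {
  if (length(feature) != length(labels)) {
    stop("feature and labels must have equal length", call. = FALSE)
  }
  cond <- 0
  for (v in unique(feature)) {
    idx <- feature == v
    cond <- cond + mean(idx) * entropy_bits(labels[idx])
  }
  entropy_bits(labels) - cond
}

#' Select features with positive information gain
#'
#' Keeps columns whose gain exceeds `threshold` (strictly, with a 1e-12
#' guard), mirroring the "information gain greater than 0" selection rule.
#'
#' @param fm An `ov_features` with labels.
#' @param threshold Gain threshold (default 0).
#' @return List with `features` (the reduced `ov_features`) and `report`
#'   (data frame of feature, info_gain, selected — sorted by gain
#'   descending).
#' @export
select_by_ig <- function(fm, threshold = 0) {
  if (is.null(fm$labels)) stop("feature matrix carries no labels", call. = FALSE)
  gains <- apply(fm$x, 2, info_gain, labels = fm$labels)
  if (ncol(fm$x) == 0) gains <- numeric(0)
  keep <- gains > threshold + 1e-12
  if (!any(keep)) {
    warning("no feature exceeds the information-gain threshold; ",
            "selection is empty", call. = FALSE)
  }
  report <- data.frame(feature = colnames(fm$x), info_gain = as.numeric(gains),
                       selected = keep, stringsAsFactors = FALSE)
  report <- report[order(-report$info_gain, report$feature), , drop = FALSE]
  rownames(report) <- NULL
  list(features = new_feature_matrix(fm$x[, keep, drop = FALSE], fm$labels),
       report = report)
}
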