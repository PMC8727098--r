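test_that("bin widths 1/2/3 months on a 36-month horizon give 36/18/12 bins", {
  expect_equal(bin_scheme(1)$n_bins, 36L)
  expect_equal(bin_scheme(2)$n_bins, 18L)
  expect_equal(bin_scheme(3)$n_bins, 12L)
  expect_error(bin_scheme(5), "divide")
  expect_error(bin_scheme(0), "positive integer")
})

test_that("gaps map to half-open bins with zero landing in T1", {
  w1 <- bin_scheme(1)
  expect_equal(bin_index(0.5, w1), 1L)       # within one month -> T1
  expect_equal(bin_index(0, w1), 1L)         # simultaneous start -> T1
  expect_equal(bin_index(1, w1), 1L)         # boundary closes the bin
  expect_equal(bin_index(1.01, w1), 2L)
  w2 <- bin_scheme(2)
  expect_equal(bin_index(35.9, w2), 18L)     # ceil(35.9 / 2)
  expect_true(is.na(bin_index(36.5, w2)))    # out of horizon: no feature
  expect_error(bin_index(-1, w2), ">= 0")
})

test_that("timed columns fire only on adjacent transitions in the right bin", {
  db <- make_db(list(c("Chemotherapy", "CRS"),
                     c("Chemotherapy", "Surgery", "CRS"),
                     c("Chemotherapy", "CRS")),
                alphabet = ov_treatments(),
                offsets = list(c(0, 9), c(0, 3, 9), c(0, 2)))
  pats <- mine_frequent_substrings(db, 0.05)
  fm <- build_timed_matrix(db, pats, bin_scheme(2))
  # gap 9 at width 2 -> T5; an interposed surgery disqualifies patient 2
  expect_equal(unname(fm$x[, "Chemotherapy_T5_CRS"]), c(1L, 0L, 0L))
  expect_equal(unname(fm$x[, "Chemotherapy_T1_CRS"]), c(0L, 0L, 1L))
  expect_false(any(grepl("Chemotherapy_T[234]_CRS", colnames(fm$x))))
  # at most 18 bins per pattern at width 2
  expect_lte(sum(grepl("^Chemotherapy_T\\d+_CRS$", colnames(fm$x))), 18)
})

test_that("two occurrences with different gaps set both bin columns", {
  db <- make_db(list(c("Surgery", "Chemotherapy", "Surgery", "Chemotherapy"),
                     c("Surgery", "Chemotherapy")),
                alphabet = ov_treatments(),
                offsets = list(c(0, 1, 10, 19), c(0, 1)))
  pats <- mine_frequent_substrings(db, 0.5)
  fm <- build_timed_matrix(db, pats, bin_scheme(2))
  expect_equal(unname(fm$x[1, c("Surgery_T1_Chemotherapy",
                                "Surgery_T5_Chemotherapy")]), c(1L, 1L))
})

test_that("single-occurrence rows have at most one bin set per pattern", {
  spec <- cohort_spec(n_patients = 80, seed = 21)
  co <- generate_cohort(spec)
  db <- build_sequence_db(co)
  pats <- mine_frequent_substrings(db, 0.05)
  fm <- build_timed_matrix(db, pats, bin_scheme(2))
  pairs <- pats[pats$length == 2, ]
  for (r in seq_len(nrow(pairs))) {
    xy <- pairs$symbols[[r]]
    cols <- grepl(sprintf("^%s_T\\d+_%s$", xy[1], xy[2]), colnames(fm$x))
    if (!any(cols)) next
    # one adjacent occurrence can set at most one bin
    single <- vapply(db$symbols, function(s) {
      sum(s[-length(s)] == xy[1] & s[-1] == xy[2]) <= 1
    }, logical(1))
    expect_true(all(rowSums(fm$x[single, cols, drop = FALSE]) <= 1))
  }
})

test_that("collapsing bins to the horizon recovers the ever-adjacent flag", {
  spec <- cohort_spec(n_patients = 60, seed = 31)
  co <- generate_cohort(spec)
  db <- build_sequence_db(co)
  pats <- mine_frequent_substrings(db, 0.05)
  fm <- build_timed_matrix(db, pats, bin_scheme(36))
  pairs <- pats[pats$length == 2, ]
  for (r in seq_len(nrow(pairs))) {
    xy <- pairs$symbols[[r]]
    ever <- vapply(seq_len(db$n), function(i) {
      s <- db$symbols[[i]]
      length(s) >= 2 && any(s[-length(s)] == xy[1] & s[-1] == xy[2])
    }, logical(1))
    col <- sprintf("%s_T1_%s", xy[1], xy[2])
    got <- if (col %in% colnames(fm$x)) fm$x[, col] else rep(0L, db$n)
    expect_equal(unname(got), as.integer(ever))
  }
})

test_that("untimed columns flag treatment presence regardless of order", {
  db <- make_db(list(c("NACT", "Surgery"), c("Surgery", "NACT"),
                     character(0)),
                alphabet = ov_treatments())
  fm <- build_untimed_matrix(db)
  expect_equal(unname(fm$x[1, ]), unname(fm$x[2, ]))
  expect_equal(unname(fm$x[1, c("NACT", "Surgery")]), c(1L, 1L))
  expect_equal(sum(fm$x[1, ]), 2)
  expect_equal(sum(fm$x[3, ]), 0)
})

test_that("entropy follows the class proportions in bits", {
  expect_equal(entropy_bits(c(0, 0, 1, 1)), 1.0)
  expect_equal(entropy_bits(rep(1, 9)), 0.0)
  expect_equal(entropy_bits(c(rep(1, 59), rep(0, 81))), 0.98211,
               tolerance = 1e-4)
})

test_that("information gain matches its defining identities", {
  y <- c(rep(1L, 6), rep(0L, 6))
  expect_equal(info_gain(y, y), entropy_bits(y))
  expect_equal(info_gain(rep(1L, 12), y), 0)
  expect_equal(info_gain(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(info_gain(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("information gain matches the contingency-table oracle (fuzzed)", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    f <- sample(0:1, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    g <- info_gain(f, y)
    expect_equal(g, ig_oracle(f, y), tolerance = 1e-10)
    expect_gte(g, -1e-12)
    expect_lte(g, entropy_bits(y) + 1e-12)
  }
})

test_that("selection keeps exactly the positive-gain columns", {
  set.seed(5)
  n <- 80
  y <- sample(0:1, n, replace = TRUE)
  x <- cbind(signal = y,                       # perfectly predictive
             constant = rep(1L, n),
             noise = sample(0:1, n, replace = TRUE))
  sel <- select_by_ig(new_feature_matrix(x, y))
  expect_true("signal" %in% colnames(sel$features$x))
  expect_false("constant" %in% colnames(sel$features$x))
  expect_equal(sel$report$feature[1], "signal")   # sorted by gain
  expect_equal(sel$report$info_gain[1], entropy_bits(y))

  # brute-force agreement on a fuzzed matrix
  xf <- matrix(sample(0:1, n * 8, replace = TRUE), n, 8,
               dimnames = list(NULL, paste0("f", 1:8)))
  self <- select_by_ig(new_feature_matrix(xf, y))
  manual <- colnames(xf)[apply(xf, 2, ig_oracle, labels = y) > 1e-12]
  expect_setequal(colnames(self$features$x), manual)

  # all-constant input: everything dropped, with a warning
  xc <- matrix(1L, n, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(out <- select_by_ig(new_feature_matrix(xc, y)),
                 "selection is empty")
  expect_equal(ncol(out$features$x), 0)
})
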