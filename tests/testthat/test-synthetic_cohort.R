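test_that("identical spec and seed give byte-identical cohorts", {
  spec <- cohort_spec(n_patients = 40, seed = 7,
                      planted_pattern = default_planted_pattern())
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  expect_false(identical(generate_cohort(spec),
                         generate_cohort(cohort_spec(n_patients = 40,
                                                     seed = 8))))
})

test_that("empirical survival tracks the target prevalence", {
  co <- generate_cohort(cohort_spec(n_patients = 140,
                                    survival_prevalence = 0.4214, seed = 7))
  expect_equal(nrow(co$patients), 140)
  frac <- mean(co$patients$survived_3yr)
  expect_gte(frac, 0.32)
  expect_lte(frac, 0.52)
})

test_that("intercept calibration holds across seeds at n = 1000", {
  fracs <- vapply(1:20, function(s) {
    mean(generate_cohort(cohort_spec(n_patients = 1000,
                                     seed = s))$patients$survived_3yr)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.4214), 0.02)
})

test_that("invalid specs fail naming the offending field", {
  expect_error(cohort_spec(n_patients = 5), "n_patients")
  expect_error(cohort_spec(survival_prevalence = 1.2), "survival_prevalence")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(planted_pattern = list(source = "Foo",
                                                  target = "CRS",
                                                  gap_range = c(2, 6),
                                                  weight = 1)),
               "planted_pattern")
})

test_that("generated records respect event invariants", {
  spec <- cohort_spec(n_patients = 100, seed = 3)
  co <- generate_cohort(spec)
  expect_true(all(co$events$treatment %in% spec$treatment_alphabet))
  expect_true(all(co$events$month_offset >= 0))
  expect_true(all(co$events$month_offset <= spec$horizon_months))
  by_pat <- split(co$events$month_offset, co$events$patient_id)
  expect_true(all(vapply(by_pat, function(o) !is.unsorted(o), logical(1))))
  expect_true(all(lengths(by_pat) <= spec$max_lines))
})

test_that("stronger planted weights widen the carrier survival gap", {
  gap_at <- function(w) {
    spec <- cohort_spec(n_patients = 2000, effect_coefficients = numeric(0),
                        planted_pattern = default_planted_pattern(weight = w),
                        seed = 5)
    co <- generate_cohort(spec)
    db <- build_sequence_db(co)
    carrier <- vapply(seq_len(db$n), function(i) {
      ovsurvmine:::has_timed_transition(db$symbols[[i]], db$offsets[[i]],
                                        spec$planted_pattern)
    }, logical(1))
    y <- co$patients$survived_3yr
    mean(y[carrier]) - mean(y[!carrier])
  }
  gaps <- vapply(c(0, 1, 2), gap_at, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("null generator makes labels independent of features", {
  spec <- cohort_spec(n_patients = 400, survival_prevalence = 0.5,
                      effect_coefficients = numeric(0), seed = 2)
  co <- generate_cohort(spec)
  # survival rate among ECOG >= 3 patients matches the rest, up to noise
  hi <- co$patients$ecog >= 3
  expect_lt(abs(mean(co$patients$survived_3yr[hi]) -
                  mean(co$patients$survived_3yr[!hi])), 0.15)
})

test_that("missingness injection is MCAR at the configured rate", {
  spec0 <- cohort_spec(n_patients = 50, missing_rate = 0, seed = 1)
  co <- generate_cohort(spec0)
  expect_identical(inject_missingness(co, spec0), co)

  spec <- cohort_spec(n_patients = 1000, missing_rate = 0.1, seed = 1)
  masked <- inject_missingness(generate_cohort(spec), spec)
  cells <- unlist(lapply(c("age", "ca125", "ascites", "grade", "stage",
                           "histology"),
                         function(f) is.na(masked$patients[[f]])))
  expect_gte(mean(cells), 0.08)
  expect_lte(mean(cells), 0.12)
  expect_false(any(is.na(masked$events$month_offset)))

  spec_lab <- cohort_spec(n_patients = 100, label_missing_rate = 0.06,
                          seed = 4)
  masked <- inject_missingness(generate_cohort(spec_lab), spec_lab)
  n_missing <- sum(is.na(masked$patients$survived_3yr))
  expect_gte(n_missing, 1)   # binomial(100, 0.06) away from the tails
  expect_lte(n_missing, 14)
})

test_that("cohorts round-trip through the two-CSV format", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = 30, seed = 9)
  co <- generate_cohort(spec)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients, co$patients)
  expect_equal(back$events, co$events)

  # a patient with no events survives the round trip with an empty sequence
  expect_true(all(co$patients$patient_id %in%
                    back$patients$patient_id))
})

test_that("malformed event logs raise parse errors naming the row", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_patients = 10, seed = 1))
  write_cohort(co, dir)

  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        colClasses = c(patient_id = "character"))
  ev$month_offset[2] <- -1
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "row 2.*negative")

  ev$month_offset[2] <- 3
  ev$treatment[3] <- "Acupuncture"
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "row 3.*unknown treatment")

  # out-of-order offsets within one patient
  ev2 <- data.frame(patient_id = c("P1", "P1"),
                    treatment = c("Surgery", "Chemotherapy"),
                    month_offset = c(10, 2))
  utils::write.csv(ev2, file.path(dir, "events.csv"), row.names = FALSE)
  p1 <- utils::read.csv(file.path(dir, "patients.csv"),
                        colClasses = c(patient_id = "character"))
  p1$patient_id[1] <- "P1"
  utils::write.csv(p1, file.path(dir, "patients.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "row 2.*out of order")
})
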