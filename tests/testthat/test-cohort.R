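test_that("reading the packaged cohort yields 26 validated records", {
  cohort <- mpm_example_cohort()
  expect_s3_class(cohort, "mpm_cohort")
  expect_identical(nrow(cohort), 26L)
  expect_false(attr(cohort, "completed"))
  expect_identical(anyDuplicated(cohort$patient_id), 0L)
  expect_true(all(cohort$n_positive <= cohort$n_biopsies_taken))
  # published cohort summaries baked into the fixture
  expect_identical(median(cohort$n_biopsies_taken), 7)
  expect_identical(range(cohort$n_biopsies_taken), c(3L, 13L))
  expect_identical(sum(cohort$n_positive), 15L)
})

test_that("read_cohort validates schema and rows", {
  # header-only file is a valid empty cohort
  empty <- write_temp_cohort(data.frame(patient_id = character(),
                                        n_biopsies_taken = integer(),
                                        n_positive = integer()))
  expect_message(co <- read_cohort(empty), "no patient rows")
  expect_identical(nrow(co), 0L)

  # missing column is named in the error
  bad <- write_temp_cohort(data.frame(patient_id = "a", n_positive = 1))
  expect_error(read_cohort(bad), "n_biopsies_taken")

  # invariant violation names the patient
  viol <- write_temp_cohort(data.frame(patient_id = "px",
                                       n_biopsies_taken = 3, n_positive = 5))
  expect_error(read_cohort(viol), "px")

  # extra columns are dropped with a warning
  extra <- write_temp_cohort(data.frame(patient_id = "a",
                                        n_biopsies_taken = 5, n_positive = 0,
                                        pci_score = 12))
  expect_warning(co <- read_cohort(extra), "pci_score")
  expect_identical(names(as.data.frame(co)),
                   c("patient_id", "n_biopsies_taken", "n_positive",
                     "height_cm", "weight_kg"))

  expect_error(read_cohort(tempfile()), "not found")
})

test_that("completion pads to the target and conserves positives", {
  co <- mpm_cohort(c("a", "b", "c"), c(6, 13, 3), c(2, 1, 0))
  done <- complete_cohort(co, 13)
  expect_true(attr(done, "completed"))
  expect_identical(done$n_biopsies_taken, rep(13L, 3))
  expect_identical(done$n_positive, co$n_positive)
  expect_identical(sum(done$n_positive), sum(co$n_positive))
  # a record already at the target is unchanged
  expect_identical(done$n_positive[2], co$n_positive[2])
  # over-target records are an error
  expect_error(complete_cohort(co, 5), "exceeds target_n")
  # default target is the cohort maximum
  expect_identical(complete_cohort(co)$n_biopsies_taken, rep(13L, 3))
})

test_that("prevalence counts patients with any positive biopsy", {
  cohort <- mpm_example_cohort()
  expect_equal(prevalence(cohort), 7 / 26)
  # invariant under completion
  expect_equal(prevalence(complete_cohort(cohort, 13)), 7 / 26)
  expect_equal(prevalence(mpm_cohort("a", 4, 0)), 0)
  expect_equal(prevalence(mpm_cohort("a", 4, 1)), 1)
  empty <- complete_cohort(mpm_cohort("a", 4, 0), 13)[0, ]
  class(empty) <- c("mpm_cohort", "data.frame")
  expect_error(prevalence(empty), "empty")
})

test_that("positive-count histogram matches the reference pattern", {
  done <- complete_cohort(mpm_example_cohort(), 13)
  h <- positive_count_histogram(done)
  expect_identical(h$support, 0:13)
  expect_equal(sum(h$freq), 1, tolerance = 1e-12)
  expect_equal(h$freq[1:3], c(19, 4, 2) / 26)
  expect_equal(h$freq[8], 1 / 26)
  expect_equal(sum(h$freq[c(4:7, 9:14)]), 0)
  # histogram requires a completed cohort
  expect_error(positive_count_histogram(mpm_example_cohort()), "completed")
  # single-patient degenerate case
  one <- complete_cohort(mpm_cohort("a", 3, 0), 13)
  h1 <- positive_count_histogram(one)
  expect_equal(h1$freq, c(1, rep(0, 13)))
})

test_that("histograms from random cohorts are proper distributions", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    taken <- sample(1:13, n, replace = TRUE)
    co <- mpm_cohort(seq_len(n), taken,
                     vapply(taken, function(t) sample(0:t, 1), integer(1)))
    h <- positive_count_histogram(complete_cohort(co, 13))
    expect_true(all(h$freq >= 0))
    expect_equal(sum(h$freq), 1, tolerance = 1e-12)
  }
})

test_that("cohort round-trips through CSV", {
  cohort <- mpm_example_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})
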