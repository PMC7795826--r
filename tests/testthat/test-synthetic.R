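test_that("degenerate burden laws force the observable extremes", {
  cfg0 <- synthetic_config(burden_law = list(values = 0L, probs = 1))
  co0 <- sample_cohort(cfg0, seed = 3)
  expect_true(all(co0$n_positive == 0L))
  cfgN <- synthetic_config(n_subsurfaces = 400L,
                           burden_law = list(values = 400L, probs = 1))
  coN <- sample_cohort(cfgN, seed = 3)
  expect_identical(coN$n_positive, coN$n_biopsies_taken)
})

test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- synthetic_config()
  a <- sample_cohort(cfg, seed = 42)
  b <- sample_cohort(cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c <- sample_cohort(cfg, seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("enlarging the cohort preserves earlier patients' draws", {
  small <- sample_cohort(synthetic_config(n_patients = 10L), seed = 7)
  large <- sample_cohort(synthetic_config(n_patients = 25L), seed = 7)
  strip <- function(co) {
    df <- data.frame(co)[, c("patient_id", "n_biopsies_taken", "n_positive",
                             "height_cm", "weight_kg")]
    rownames(df) <- NULL
    df
  }
  expect_identical(strip(large)[1:10, ], strip(small))
  expect_identical(attr(large, "truth")$true_K[1:10],
                   attr(small, "truth")$true_K)
})

test_that("positive counts have the hypergeometric mean n K / N", {
  K <- 300L; N <- 4000L
  cfg <- synthetic_config(n_patients = 50L, n_subsurfaces = N,
                          burden_law = list(values = K, probs = 1))
  draws <- unlist(lapply(1:60, function(i) {
    co <- sample_cohort(cfg, seed = 2000 + i)
    co$n_positive / co$n_biopsies_taken
  }))
  # per-draw positive fraction has mean K/N; check within 3 standard errors
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - K / N), 3 * se)
})

test_that("synthetic heights and weights emulate the published anthropometry", {
  cfg <- synthetic_config(n_patients = 400L)
  co <- sample_cohort(cfg, seed = 12)
  bsa <- body_surface_area(co$height_cm, co$weight_kg, "dubois")
  expect_equal(mean(bsa), 1.65, tolerance = 0.03)
})

test_that("recovery experiment reports bias and RMSE against the known truth", {
  # zero-burden truth: every replicate estimates exactly zero
  cfg0 <- synthetic_config(n_patients = 8L, n_subsurfaces = 300L,
                           burden_law = list(values = 0L, probs = 1))
  r0 <- recovery_experiment(cfg0, n_replicates = 3, seed = 5)
  expect_equal(r0$truth, 0)
  expect_equal(r0$mean_estimate, 0, tolerance = 1e-6)
  expect_identical(r0$n_failed, 0L)

  # two-point truth on a reduced grid: estimates concentrate near the truth
  cfg <- synthetic_config(n_patients = 26L, n_subsurfaces = 800L,
                          burden_law = list(values = c(0L, 60L),
                                            probs = c(0.25, 0.75)))
  r <- recovery_experiment(cfg, n_replicates = 12, seed = 21)
  expect_identical(r$n_failed, 0L)
  expect_lt(abs(r$bias), 0.35)
  expect_equal(nrow(r$estimates), 12L)
})

test_that("more patients reduce the recovery error", {
  law <- list(values = c(0L, 60L), probs = c(0.3, 0.7))
  rmse <- vapply(c(15L, 60L, 240L), function(np) {
    cfg <- synthetic_config(n_patients = np, n_subsurfaces = 800L,
                            burden_law = law)
    recovery_experiment(cfg, n_replicates = 40, seed = 33)$rmse
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("padding truncated cohorts does not inflate the residual probability", {
  # paired comparison: the same latent cohorts analysed with all 13 biopsies
  # versus truncated to 3..13 and padded back to 13 with negatives
  N <- 500L
  H <- build_forward_matrix(N, 13L)
  law <- list(values = c(0L, 40L), probs = c(0.3, 0.7))
  full_cfg <- synthetic_config(n_patients = 26L, n_subsurfaces = N,
                               burden_law = law,
                               biopsy_count_law = list(values = 13L, probs = 1))
  est <- function(cohort) {
    pois <- fit_poisson_ls(positive_count_histogram(
      complete_cohort(cohort, 13)))
    residual_probability(invert_burden(pois, H))
  }
  diffs <- vapply(1:100, function(i) {
    full <- sample_cohort(full_cfg, seed = 9000 + i)
    set.seed(600 + i)
    kept <- sample(3:13, nrow(full), replace = TRUE)
    # positives retained in a random subset of the 13 biopsies
    trunc_pos <- rhyper(nrow(full), m = full$n_positive,
                        n = 13L - full$n_positive, k = kept)
    trunc <- mpm_cohort(full$patient_id, kept, trunc_pos)
    est(trunc) - est(full)
  }, numeric(1))
  expect_lte(mean(diffs), 0.01)   # padding may lower, must not raise
})
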