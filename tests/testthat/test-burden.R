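test_that("hypergeometric pmf matches the product-formula oracle", {
  # no affected sub-surface: certainly zero positives
  expect_equal(hypergeom_pmf(0, 4000, 0, 13), 1)
  # all affected: every biopsy positive
  expect_equal(hypergeom_pmf(13, 4000, 4000, 13), 1)
  # P(X = 0 | K = 400) as a telescoping product over the 13 draws
  oracle <- prod((3600 - 0:12) / (4000 - 0:12))
  expect_equal(hypergeom_pmf(0, 4000, 400, 13), oracle, tolerance = 1e-12)
  expect_error(hypergeom_pmf(0, 4000, 4001, 13), "K")
  expect_error(hypergeom_pmf(14, 4000, 10, 13), "x")
})

test_that("forward matrix is column-stochastic with the right corner columns", {
  H <- build_forward_matrix(4000L, 13L)
  expect_identical(dim(unclass(H)), c(14L, 4001L))
  expect_lt(max(abs(colSums(unclass(H)) - 1)), 1e-10)
  expect_equal(unclass(H)[, 1], c(1, rep(0, 13)))          # K = 0
  expect_equal(unclass(H)[, 4001], c(rep(0, 13), 1))       # K = N
  expect_error(build_forward_matrix(10L, 13L), "exceed")
})

test_that("a certain-negative biopsy profile inverts to no burden", {
  H <- build_forward_matrix(4000L, 13L)
  b <- invert_burden(c(1, rep(0, 13)), H)
  expect_equal(b$p[1], 1, tolerance = 1e-6)
  expect_equal(residual_probability(b), 0, tolerance = 1e-6)
})

test_that("forward-then-invert recovers coarse-grid truths", {
  H <- build_forward_matrix(4000L, 13L)
  p_true <- numeric(4001)
  p_true[1] <- 0.3
  p_true[501] <- 0.7                      # K = 500
  q <- as.numeric(unclass(H) %*% p_true)
  b <- invert_burden(q, H)
  expect_lte(b$residual_fit, 1e-10)       # the truth is feasible
  expect_equal(residual_probability(b), 0.7, tolerance = 0.02)

  # a three-point truth
  p3 <- numeric(4001)
  p3[c(1, 201, 1001)] <- c(0.15, 0.45, 0.40)
  q3 <- as.numeric(unclass(H) %*% p3)
  b3 <- invert_burden(q3, H)
  expect_lte(b3$residual_fit, 1e-10)
  expect_equal(residual_probability(b3), 0.85, tolerance = 0.02)
})

test_that("inversion rejects malformed inputs", {
  H <- build_forward_matrix(100L, 13L)
  expect_error(invert_burden(rep(1 / 10, 10), H), "nrow")
  expect_error(invert_burden(c(2, rep(0, 13)), H), "probability")
  expect_error(invert_burden(c(-1, 2, rep(0, 12)), H), "probability")
})

test_that("survival function enumerates tail probabilities and ends at zero", {
  b <- structure(list(p = c(0.5, 0.3, 0.2), K = 0:2), class = "mpm_burden")
  S <- survival_function(b)
  expect_equal(as.numeric(S), c(0.5, 0.2, 0))
  expect_true(all(diff(as.numeric(S)) <= 1e-15))

  d0 <- structure(list(p = c(1, 0, 0, 0), K = 0:3), class = "mpm_burden")
  expect_equal(as.numeric(survival_function(d0)), rep(0, 4))
})

test_that("tail sums reproduce the mean of random burden distributions", {
  set.seed(99)
  for (i in 1:10) {
    p <- runif(200)^2
    p <- p / sum(p)
    b <- structure(list(p = p, K = 0:199), class = "mpm_burden")
    S <- survival_function(b)
    expect_equal(sum(as.numeric(S)), sum((0:199) * p), tolerance = 1e-10)
  }
})

test_that("spread quantiles use the smallest-n tie rule and are monotone in alpha", {
  b <- structure(list(p = c(0.5, 0.3, 0.2), K = 0:2), class = "mpm_burden")
  S <- survival_function(b)                  # S = (0.5, 0.2, 0)
  expect_identical(spread_quantile(S, 0.5), 0L)
  expect_identical(spread_quantile(S, 0.49), 1L)
  expect_identical(spread_quantile(S, 0.2), 1L)
  expect_identical(spread_quantile(S, 0.1), 2L)
  expect_error(spread_quantile(S, 0), "alpha")
  expect_error(spread_quantile(S, 1), "alpha")

  set.seed(7)
  p <- runif(500)^3
  p <- p / sum(p)
  S <- survival_function(structure(list(p = p, K = 0:499),
                                   class = "mpm_burden"))
  alphas <- seq(0.02, 0.98, by = 0.02)
  qs <- spread_quantile(S, alphas)
  expect_true(all(diff(qs) <= 0))

  # point mass at zero: every quantile is zero
  d0 <- survival_function(structure(list(p = c(1, rep(0, 9)), K = 0:9),
                                    class = "mpm_burden"))
  expect_identical(spread_quantile(d0, 0.5), 0L)
})

test_that("spread fractions convert counts to surface proportions", {
  expect_equal(spread_fraction(69, 4000), 69 / 4000)
  expect_equal(spread_fraction(105, 4000), 105 / 4000)
  expect_equal(spread_fraction(0, 4000), 0)
  grid <- subsurface_grid(4000)
  expect_equal(spread_fraction(69, grid), 0.01725)
  expect_error(spread_fraction(4001, grid), "n must")
})
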