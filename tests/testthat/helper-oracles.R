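# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# The reference cohort's positive-biopsy counts after completion to 13:
# 19 patients with 0, four with 1, two with 2, one with 7.
reference_histogram <- function() {
  relative_histogram(0:13, c(19, 4, 2, 0, 0, 0, 0, 1, rep(0, 6)) / 26,
                     n_patients = 26L)
}

# 1-D grid search for the least-squares Poisson rate (step 1e-4 on [0, 3]).
grid_search_lambda <- function(freq, support = 0:13,
                               grid = seq(0, 3, by = 1e-4)) {
  sse <- vapply(grid, function(l) sum((dpois(support, l) - freq)^2),
                numeric(1))
  grid[which.min(sse)]
}

# All compositions of `total` into `k` non-negative parts (ordered), as a
# matrix with k columns; used for brute-force search over the discretised
# simplex.
compositions <- function(total, k) {
  if (k == 1L) return(matrix(total, ncol = 1L))
  out <- vector("list", total + 1L)
  for (first in 0:total) {
    rest <- compositions(total - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Temporary cohort CSV writer for read_cohort tests.
write_temp_cohort <- function(df, ...) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE, ...)
  path
}
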