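#' Fit a Poisson distribution to the positive-count histogram
#'
#' Least-squares fit of the Poisson probability mass function to the relative
#' histogram of positive-biopsy counts: the rate `lambda` minimises
#' `sum_x (dpois(x, lambda) - freq(x))^2` over `[0, lambda_max]`. The fitted
#' pmf is evaluated on the histogram support `0:n` and renormalised there, so
#' that the downstream law-of-total-probability step receives a proper
#' distribution on the observable counts.
#'
#' The objective is minimised by a coarse grid scan followed by golden-section
#' refinement on the bracketing interval, which guards against local minima.
#'
#' @param hist an `mpm_histogram` (see [positive_count_histogram()]).
#' @param lambda_max upper search bound for the rate; defaults to the support
#'   maximum.
#' @return an object of class `mpm_poisson_fit`: list with `lambda`,
#'   `fitted_pmf` (renormalised on the support), `loss` (sum of squared
#'   residuals at `lambda`), `method`, and `support`.
#' @seealso [fit_poisson_mle()] for the moment/maximum-likelihood cross-check.
#' @export
fit_poisson_ls <- function(hist, lambda_max = NULL) {
  stopifnot(inherits(hist, "mpm_histogram"))
  x <- hist$support
  f <- hist$freq
  if (is.null(lambda_max)) lambda_max <- max(x)
  if (f[1L] >= 1 - 1e-15) {
    message("all histogram mass at zero: returning lambda = 0 (point mass)")
    return(new_poisson_fit(0, x, f, method = "least_squares"))
  }
  objective <- function(l) sum((dpois(x, l) - f)^2)
  grid <- seq(0, lambda_max, by = 0.05)
  vals <- vapply(grid, objective, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(objective, c(lo, hi), tol = 1e-10)
  lam <- opt$minimum
  if (objective(0) <= opt$objective) lam <- 0  # boundary beats interior
  new_poisson_fit(lam, x, f, method = "least_squares")
}

#' Moment (maximum-likelihood) Poisson fit
#'
#' Sets the rate to the histogram mean, `lambda = sum(x * freq(x))`, which is
#' the maximum-likelihood estimate for untruncated Poisson counts. Provided
#' as a cross-check on the least-squares fit.
#'
#' @inheritParams fit_poisson_ls
#' @return an `mpm_poisson_fit` with `method = "mle"`.
#' @export
fit_poisson_mle <- function(hist) {
  stopifnot(inherits(hist, "mpm_histogram"))
  lam <- sum(hist$support * hist$freq)
  new_poisson_fit(lam, hist$support, hist$freq, method = "mle")
}

new_poisson_fit <- function(lambda, support, freq, method) {
  pmf <- dpois(support, lambda)
  z <- sum(pmf)
  # truncation mass above max(support) is negligible for the rates met here,
  # but renormalise so the vector is a proper distribution on 0..n
  pmf <- pmf / z
  structure(list(
    lambda = lambda,
    fitted_pmf = pmf,
    truncation_constant = z,
    loss = sum((dpois(support, lambda) - freq)^2),
    method = method,
    support = support
  ), class = "mpm_poisson_fit")
}

#' Fitted biopsy-count distribution
#'
#' The probability vector q over 0..n positive biopsies implied by a Poisson
#' fit; the input to the burden inversion.
#'
#' @param fit an `mpm_poisson_fit`.
#' @return numeric probability vector over the fit support (sums to 1).
#' @export
biopsy_count_pmf <- function(fit) {
  stopifnot(inherits(fit, "mpm_poisson_fit"))
  fit$fitted_pmf
}

#' @export
print.mpm_poisson_fit <- function(x, ...) {
  cat("<mpm_poisson_fit> lambda = ", format(x$lambda, digits = 6),
      " (", x$method, "), SSR = ", format(x$loss, digits = 4),
      ", support 0..", max(x$support), "\n", sep = "")
  invisible(x)
}
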