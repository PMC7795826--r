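#' Hypergeometric sampling probability
#'
#' Probability of observing `x` positive biopsies when `n` biopsy-sized
#' patches are sampled without replacement from `N` sub-surfaces of which `K`
#' harbour microscopic disease:
#' `choose(K, x) * choose(N - K, n - x) / choose(N, n)`, zero outside the
#' support. Computed in log space via [stats::dhyper()].
#'
#' @param x observed positive count(s), `0 <= x <= n`.
#' @param N total number of sub-surfaces.
#' @param K number of affected sub-surfaces, `0 <= K <= N`; vectorised.
#' @param n number of biopsies drawn, `0 <= n <= N`.
#' @return probability (vectorised over `x` and `K`).
#' @export
hypergeom_pmf <- function(x, N, K, n) {
  if (any(K < 0) || any(K > N)) stop("K must satisfy 0 <= K <= N")
  if (n < 0 || n > N) stop("n must satisfy 0 <= n <= N")
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  dhyper(x, m = K, n = N - K, k = n)
}

#' Forward mixture matrix of the sampling model
#'
#' The `(n_draws + 1) x (N + 1)` matrix `H` with
#' `H[x + 1, K + 1] = P(x positives | K affected)` given by the
#' hypergeometric law. By the law of total probability, the marginal
#' distribution of the positive-biopsy count is `q = H p` where `p` is the
#' burden distribution over `K = 0..N`. Every column sums to 1.
#'
#' @param grid an `mpm_grid` (or a single integer N).
#' @param n_draws biopsies per patient (default 13); must not exceed N.
#' @return matrix of class `mpm_forward` with attributes `N` and `n_draws`.
#' @export
build_forward_matrix <- function(grid, n_draws = 13L) {
  N <- if (inherits(grid, "mpm_grid")) grid$n_subsurfaces else as.integer(grid)
  n_draws <- as.integer(n_draws)
  if (n_draws > N) stop("n_draws must not exceed the number of sub-surfaces N")
  H <- outer(0:n_draws, 0:N, function(x, K) dhyper(x, K, N - K, n_draws))
  structure(H, class = c("mpm_forward", "matrix"), N = N, n_draws = n_draws)
}

#' Invert the sampling model for the burden distribution
#'
#' Recovers the cohort-level distribution `p(K)` of the number of affected
#' sub-surfaces from the fitted biopsy-count distribution `q`, by
#' simplex-constrained least squares:
#' `min ||H p - q||^2 + lambda_reg ||p||^2` subject to `p >= 0`,
#' `sum(p) = 1`. With only `n_draws + 1` observable counts and `N + 1`
#' unknowns the fit constraints leave a face of equally good solutions; the
#' ridge term selects its minimum-norm point, making the output unique and
#' reproducible (see [simplex_ls()]).
#'
#' @param q probability vector over `0..n_draws` (e.g. from
#'   [biopsy_count_pmf()]), or an `mpm_poisson_fit`.
#' @param H forward matrix from [build_forward_matrix()].
#' @param lambda_reg ridge weight (default 1e-8); `0` disables regularisation
#'   (the result is then one of many minimisers).
#' @param ... further arguments passed to [simplex_ls()].
#' @return an object of class `mpm_burden`: list with `p` (probabilities for
#'   `K = 0..N`), `K`, `residual_fit` (achieved `||Hp - q||^2`),
#'   `objective`, `lambda_reg`, `converged`.
#' @export
invert_burden <- function(q, H, lambda_reg = 1e-8, ...) {
  if (inherits(q, "mpm_poisson_fit")) q <- biopsy_count_pmf(q)
  stopifnot(inherits(H, "mpm_forward"))
  if (length(q) != nrow(H)) {
    stop("length(q) must equal nrow(H) = n_draws + 1")
  }
  if (any(q < 0) || abs(sum(q) - 1) > 1e-9) {
    stop("q must be a probability vector (non-negative, summing to 1)")
  }
  sol <- simplex_ls(unclass(H), q, lambda_reg = lambda_reg, ...)
  if (!isTRUE(sol$converged)) {
    stop("burden inversion did not converge; kkt_residual = ",
         format(sol$kkt_residual), ", iterations = ", sol$iterations)
  }
  p <- sol$p
  if (abs(sum(p) - 1) > 1e-9) stop("solver returned an unnormalised p")
  p <- pmax(p, 0)
  p <- p / sum(p)
  structure(list(p = p, K = 0:attr(H, "N"),
                 residual_fit = sol$fit_objective,
                 objective = sol$objective,
                 lambda_reg = lambda_reg,
                 converged = sol$converged),
            class = "mpm_burden")
}

#' Probability of residual microscopic disease
#'
#' `P(K >= 1) = 1 - p(0)`: the probability that at least one sub-surface of
#' the peritoneum still harbours a microscopic metastasis after complete
#' macroscopic cytoreduction.
#'
#' @param burden an `mpm_burden`.
#' @return probability in \[0, 1\].
#' @export
residual_probability <- function(burden) {
  stopifnot(inherits(burden, "mpm_burden"))
  1 - burden$p[1L]
}

#' Survival function of the burden distribution
#'
#' `S(n) = P(K > n)` for `n = 0..N`; non-increasing with `S(N) = 0`.
#'
#' @param burden an `mpm_burden`.
#' @return numeric vector `S` of length `N + 1`, where `S[n + 1] = P(K > n)`,
#'   with class `mpm_survival`.
#' @export
survival_function <- function(burden) {
  stopifnot(inherits(burden, "mpm_burden"))
  p <- burden$p
  S <- c(rev(cumsum(rev(p)))[-1L], 0)
  structure(S, class = "mpm_survival", N = length(p) - 1L)
}

#' Spread quantile of the burden distribution
#'
#' The smallest `n` such that `P(K > n) <= alpha`. These are the tail
#' indicators of microscopic spread: e.g. `alpha = 0.95` gives the number of
#' sub-surfaces exceeded with 95% probability. Since `S` is a step function,
#' the smallest-`n` tie rule makes the quantile well defined and monotone
#' non-increasing in `alpha`.
#'
#' @param S an `mpm_survival` (or numeric survival vector with
#'   `S[n + 1] = P(K > n)`).
#' @param alpha probability level(s), strictly between 0 and 1.
#' @return integer quantile(s) `n(alpha)`.
#' @export
spread_quantile <- function(S, alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie strictly in (0, 1)")
  vapply(alpha, function(a) {
    as.integer(min(which(S <= a)) - 1L)
  }, integer(1))
}

#' Affected fraction of the peritoneal surface
#'
#' Converts a sub-surface count into the fraction of the peritoneal surface
#' it represents, `n / N`.
#'
#' @param n sub-surface count(s), `0 <= n <= N`.
#' @param grid an `mpm_grid` or integer N.
#' @return proportion(s) in \[0, 1\].
#' @export
spread_fraction <- function(n, grid) {
  N <- if (inherits(grid, "mpm_grid")) grid$n_subsurfaces else as.integer(grid)
  if (any(n < 0) || any(n > N)) stop("n must satisfy 0 <= n <= N")
  n / N
}

#' @export
print.mpm_burden <- function(x, ...) {
  cat("<mpm_burden> p(K), K = 0..", max(x$K), "\n", sep = "")
  cat("  P(K >= 1) = ", format(residual_probability(x), digits = 6),
      "   fit residual = ", format(x$residual_fit, digits = 3), "\n", sep = "")
  invisible(x)
}
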