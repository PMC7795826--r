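#' Fit the occult-burden model to a biopsy cohort
#'
#' Runs the full inference pipeline on a cohort of per-patient biopsy
#' results:
#' \enumerate{
#'   \item complete the cohort to a uniform number of biopsies per patient
#'     (padding with negative biopsies);
#'   \item build the relative histogram of positive-biopsy counts and fit a
#'     Poisson distribution to it;
#'   \item discretise the peritoneum into `N` biopsy-sized sub-surfaces
#'     (from the cohort's body measurements unless overridden);
#'   \item invert the hypergeometric sampling model by simplex-constrained
#'     least squares for the burden distribution `p(K)`, and summarise it by
#'     the residual-disease probability `P(K >= 1)` and tail quantiles.
#' }
#'
#' @param cohort an `mpm_cohort` (see [read_cohort()], [mpm_cohort()],
#'   [mpm_example_cohort()]).
#' @param target_n uniform biopsy count used for completion (default 13).
#' @param fit_method `"ls"` (least squares on the relative histogram, the
#'   default) or `"mle"` (histogram mean).
#' @param n_subsurfaces override for N. If `NULL`, N is derived from
#'   `peritoneal_area_cm2` when given, otherwise estimated from the cohort's
#'   height/weight via [cohort_subsurface_grid()].
#' @param peritoneal_area_cm2 optional fixed peritoneal area; the reference
#'   configuration uses 16,000 cm2 (giving N = 4000).
#' @param biopsy_area_cm2 area of one biopsy in cm2 (default 4).
#' @param bsa_formula body-surface-area formula, `"dubois"` or `"mosteller"`.
#' @param lambda_reg ridge weight of the inversion (default 1e-8).
#' @param alphas probability levels for the spread quantiles.
#' @param ... further arguments passed to [simplex_ls()].
#' @return an object of class `mpm_fit` with components `cohort` (completed),
#'   `histogram`, `poisson`, `grid`, `forward`, `burden`,
#'   `residual_probability`, `survival`, `quantiles`, `call`.
#' @examples
#' fit <- mpm_fit(mpm_example_cohort(), peritoneal_area_cm2 = 16000)
#' fit
#' coef(fit)
#' predict(fit, alpha = c(0.25, 0.95))
#' @export
mpm_fit <- function(cohort, target_n = 13L,
                    fit_method = c("ls", "mle"),
                    n_subsurfaces = NULL,
                    peritoneal_area_cm2 = NULL,
                    biopsy_area_cm2 = 4,
                    bsa_formula = "dubois",
                    lambda_reg = 1e-8,
                    alphas = c(0.05, 0.25, 0.50, 0.75, 0.95),
                    ...) {
  stopifnot(inherits(cohort, "mpm_cohort"))
  fit_method <- match.arg(fit_method)
  if (!is_completed(cohort)) cohort <- complete_cohort(cohort, target_n)
  n_draws <- cohort$n_biopsies_taken[1L]

  hist <- positive_count_histogram(cohort)
  pois <- switch(fit_method,
                 ls = fit_poisson_ls(hist),
                 mle = fit_poisson_mle(hist))

  grid <- if (!is.null(n_subsurfaces)) {
    subsurface_grid(n_subsurfaces, biopsy_area_cm2)
  } else if (!is.null(peritoneal_area_cm2)) {
    subsurface_grid(subsurface_count(peritoneal_area_cm2, biopsy_area_cm2),
                    biopsy_area_cm2, peritoneal_area_cm2)
  } else {
    cohort_subsurface_grid(cohort, biopsy_area_cm2, bsa_formula)
  }

  H <- build_forward_matrix(grid, n_draws)
  burden <- invert_burden(pois, H, lambda_reg = lambda_reg, ...)
  S <- survival_function(burden)
  qn <- spread_quantile(S, alphas)

  structure(list(
    cohort = cohort,
    histogram = hist,
    poisson = pois,
    grid = grid,
    forward = H,
    burden = burden,
    residual_probability = residual_probability(burden),
    survival = S,
    quantiles = stats::setNames(qn, paste0(100 * alphas, "%")),
    alphas = alphas,
    call = match.call()
  ), class = "mpm_fit")
}

#' @export
print.mpm_fit <- function(x, ...) {
  cat("Occult peritoneal burden model\n")
  cat("  cohort: ", nrow(x$cohort), " patients, ",
      x$cohort$n_biopsies_taken[1L], " biopsies each after completion\n",
      sep = "")
  cat("  Poisson rate (", x$poisson$method, "): lambda = ",
      format(x$poisson$lambda, digits = 5), "\n", sep = "")
  cat("  grid: N = ", x$grid$n_subsurfaces, " sub-surfaces of ",
      x$grid$biopsy_area_cm2, " cm2\n", sep = "")
  cat("  P(at least one residual mPM) = ",
      sprintf("%.2f%%", 100 * x$residual_probability), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mpm_fit <- function(object, ...) {
  qa <- object$quantiles
  frac <- spread_fraction(qa, object$grid)
  structure(list(
    n_patients = nrow(object$cohort),
    n_draws = object$cohort$n_biopsies_taken[1L],
    prevalence = prevalence(object$cohort),
    lambda = object$poisson$lambda,
    fit_method = object$poisson$method,
    fit_loss = object$poisson$loss,
    N = object$grid$n_subsurfaces,
    residual_probability = object$residual_probability,
    quantiles = qa,
    quantile_fractions = frac,
    inversion_residual = object$burden$residual_fit,
    lambda_reg = object$burden$lambda_reg
  ), class = "summary.mpm_fit")
}

#' @export
print.summary.mpm_fit <- function(x, ...) {
  cat("Occult peritoneal burden model\n\n")
  cat(sprintf("Patients: %d (biopsy-detected mPM prevalence %.1f%%)\n",
              x$n_patients, 100 * x$prevalence))
  cat(sprintf("Biopsies per patient after completion: %d\n", x$n_draws))
  cat(sprintf("Poisson fit (%s): lambda = %.5f, SSR = %.3e\n",
              x$fit_method, x$lambda, x$fit_loss))
  cat(sprintf("Sub-surface grid: N = %d\n", x$N))
  cat(sprintf("Inversion residual ||Hp - q||^2 = %.3e (ridge %.1e)\n",
              x$inversion_residual, x$lambda_reg))
  cat(sprintf("\nP(at least one residual mPM) = %.2f%%\n",
              100 * x$residual_probability))
  cat("\nSpread quantiles n(alpha) with P(K > n) <= alpha:\n")
  tab <- rbind(`n (sub-surfaces)` = x$quantiles,
               `fraction of peritoneum` = sprintf("%.2f%%",
                                                  100 * x$quantile_fractions))
  print(tab, quote = FALSE)
  invisible(x)
}

#' @export
coef.mpm_fit <- function(object, ...) {
  c(lambda = object$poisson$lambda,
    p0 = object$burden$p[1L],
    residual_probability = object$residual_probability)
}

#' Spread quantiles from a fitted burden model
#'
#' @param object an `mpm_fit`.
#' @param alpha probability level(s) in (0, 1); defaults to the levels used
#'   at fit time.
#' @param ... unused.
#' @return named integer vector of quantiles `n(alpha)`.
#' @export
predict.mpm_fit <- function(object, alpha = object$alphas, ...) {
  stats::setNames(spread_quantile(object$survival, alpha),
                  paste0(100 * alpha, "%"))
}

#' Residuals of a fitted burden model
#'
#' @param object an `mpm_fit`.
#' @param type `"histogram"` for the Poisson-fit residuals
#'   (`fitted pmf - observed frequency` over 0..n), or `"inversion"` for the
#'   forward-model residuals (`H p - q`).
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.mpm_fit <- function(object, type = c("histogram", "inversion"), ...) {
  type <- match.arg(type)
  switch(type,
    histogram = dpois(object$histogram$support, object$poisson$lambda) -
      object$histogram$freq,
    inversion = as.numeric(unclass(object$forward) %*% object$burden$p) -
      biopsy_count_pmf(object$poisson)
  )
}

#' Simulate cohorts from a fitted burden model
#'
#' Draws synthetic cohorts using the fitted burden distribution as the truth:
#' each simulated patient receives a latent `K` from `p(K)`, a biopsy count
#' resampled from the observed (pre-completion, when available) counts, and a
#' hypergeometric positive count.
#'
#' @param object an `mpm_fit`.
#' @param nsim number of cohorts.
#' @param seed integer seed (stored in the result as for [stats::simulate()]).
#' @param ... unused.
#' @return list of `mpm_cohort` objects, each with a `truth` attribute.
#' @export
simulate.mpm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- synthetic_config(
    n_patients = nrow(object$cohort),
    n_subsurfaces = object$grid$n_subsurfaces,
    burden_law = object$burden$p,
    biopsy_count_law = table_to_law(object$cohort$n_biopsies_taken)
  )
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^30))
  out <- lapply(seq_len(nsim), function(i) {
    sample_cohort(cfg, seed = seed + (i - 1L) * 1000L)
  })
  attr(out, "seed") <- seed
  out
}

table_to_law <- function(counts) {
  tab <- table(counts)
  list(values = as.integer(names(tab)), probs = as.numeric(tab) / sum(tab))
}

#' Plot a fitted burden model
#'
#' Two panels: the relative histogram of positive-biopsy counts with the
#' fitted Poisson pmf, and the inferred burden distribution `p(K)` zoomed on
#' the region holding 99.9% of its mass.
#'
#' @param x an `mpm_fit`.
#' @param ... unused.
#' @export
plot.mpm_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))
  on.exit(par(op))
  h <- x$histogram
  bp <- barplot(h$freq, names.arg = h$support, col = "steelblue",
                xlab = "positive biopsies per patient",
                ylab = "relative frequency",
                main = "Histogram and Poisson fit")
  points(bp, dpois(h$support, x$poisson$lambda), pch = 18, col = "darkorange",
         cex = 1.4)
  legend("topright", legend = c("observed", "Poisson fit"),
         pch = c(15, 18), col = c("steelblue", "darkorange"), bty = "n")
  p <- x$burden$p
  upper <- max(which(cumsum(p) <= 0.999), 1L) + 1L
  plot(0:(upper - 1), p[seq_len(upper)], type = "h", col = "firebrick",
       xlab = "affected sub-surfaces K", ylab = "probability",
       main = "Inferred burden p(K)")
  invisible(x)
}
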