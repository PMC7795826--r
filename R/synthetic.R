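#' Configuration for synthetic cohorts
#'
#' Describes the generative model the analysis assumes: each patient carries
#' a latent number `K` of affected sub-surfaces drawn from `burden_law`,
#' takes a number of biopsies drawn from `biopsy_count_law`, and yields a
#' hypergeometric positive count. The defaults emulate the reference study:
#' 26 patients, N = 4000 sub-surfaces, 3 to 13 biopsies per patient, body
#' measurements giving a mean body surface area of about 1.65 m2.
#'
#' @param n_patients number of patients per cohort (default 26).
#' @param n_subsurfaces N, the number of sub-surfaces (default 4000).
#' @param burden_law distribution of `K`: either a probability vector over
#'   `0:N`, or a list `list(values=, probs=)` giving a finite mixture of
#'   point masses (default: mass 0.02 at K = 0 and 0.98 at K = 300, a
#'   two-point law with analytic truth `P(K >= 1) = 0.98`).
#' @param biopsy_count_law distribution of biopsies per patient, as
#'   `list(values=, probs=)` (default uniform on 3..13).
#' @param height_mean,height_sd,weight_mean,weight_sd normal laws for body
#'   measurements (defaults 161/6 cm and 62/9 kg, matching a mean body
#'   surface area of about 1.65 m2 under Du Bois).
#' @return an object of class `mpm_synth_config`.
#' @export
synthetic_config <- function(n_patients = 26L,
                             n_subsurfaces = 4000L,
                             burden_law = list(values = c(0L, 300L),
                                               probs = c(0.02, 0.98)),
                             biopsy_count_law = list(values = 3:13,
                                                     probs = rep(1 / 11, 11)),
                             height_mean = 161, height_sd = 6,
                             weight_mean = 62, weight_sd = 9) {
  n_patients <- as.integer(n_patients)
  n_subsurfaces <- as.integer(n_subsurfaces)
  stopifnot(n_patients >= 1L, n_subsurfaces >= 1L)
  burden_law <- normalise_law(burden_law, n_subsurfaces)
  biopsy_count_law <- normalise_law(biopsy_count_law, n_subsurfaces,
                                    min_value = 1L)
  structure(list(n_patients = n_patients, n_subsurfaces = n_subsurfaces,
                 burden_law = burden_law, biopsy_count_law = biopsy_count_law,
                 height_mean = height_mean, height_sd = height_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd),
            class = "mpm_synth_config")
}

normalise_law <- function(law, N, min_value = 0L) {
  if (is.numeric(law) && is.null(names(law)) && length(law) > 2 &&
      !is.list(law)) {
    # explicit probability vector over 0..N
    if (length(law) != N + 1L) {
      stop("an explicit burden probability vector must have length N + 1")
    }
    law <- list(values = 0:N, probs = as.numeric(law))
  }
  if (!is.list(law) || !all(c("values", "probs") %in% names(law))) {
    stop("a law must be list(values=, probs=) or a probability vector over 0..N")
  }
  vals <- as.integer(law$values)
  probs <- as.numeric(law$probs)
  if (length(vals) != length(probs)) stop("values and probs lengths differ")
  if (any(probs < 0)) stop("law probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) stop("law probabilities must sum to 1")
  if (any(vals < min_value) || any(vals > N)) {
    stop("law support must lie in ", min_value, "..", N)
  }
  keep <- probs > 0
  list(values = vals[keep], probs = probs[keep] / sum(probs[keep]))
}

law_zero_mass <- function(law) {
  sum(law$probs[law$values == 0L])
}

draw_law <- function(law, n) {
  law$values[sample.int(length(law$values), n, replace = TRUE,
                        prob = law$probs)]
}

#' Sample a synthetic cohort
#'
#' Per patient: draw the latent burden `K` from the configured law, the
#' biopsy count `n_i`, and the positive count `x_i ~ Hypergeometric(N, K,
#' n_i)`; heights and weights are normal (truncated to positive). Each
#' patient consumes an independent, counter-derived random substream, so
#' enlarging the cohort does not perturb earlier patients' draws.
#'
#' @param cfg an `mpm_synth_config`.
#' @param seed integer seed; identical `cfg` and `seed` reproduce the cohort
#'   exactly.
#' @return an `mpm_cohort` with attributes `truth` (data frame `patient_id`,
#'   `true_K`) and `config`.
#' @export
sample_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "mpm_synth_config"))
  seed <- as.integer(seed)
  N <- cfg$n_subsurfaces
  n_pat <- cfg$n_patients
  K <- integer(n_pat); nb <- integer(n_pat); x <- integer(n_pat)
  h <- numeric(n_pat); w <- numeric(n_pat)
  for (i in seq_len(n_pat)) {
    # counter-based substream: one fixed-offset seed per patient
    set.seed((seed + i * 7919L) %% .Machine$integer.max)
    K[i] <- draw_law(cfg$burden_law, 1L)
    nb[i] <- draw_law(cfg$biopsy_count_law, 1L)
    x[i] <- rhyper(1L, m = K[i], n = N - K[i], k = nb[i])
    h[i] <- max(120, rnorm(1L, cfg$height_mean, cfg$height_sd))
    w[i] <- max(30, rnorm(1L, cfg$weight_mean, cfg$weight_sd))
  }
  cohort <- mpm_cohort(sprintf("S%04d", seq_len(n_pat)), nb, x,
                       round(h), round(w, 1),
                       max_biopsies = max(cfg$biopsy_count_law$values))
  attr(cohort, "truth") <- data.frame(patient_id = cohort$patient_id,
                                      true_K = K, stringsAsFactors = FALSE)
  attr(cohort, "config") <- cfg
  cohort
}

#' Parameter-recovery experiment
#'
#' Simulates replicate cohorts under a known burden law, runs the full
#' pipeline (completion, histogram, Poisson fit, inversion) on each, and
#' compares the estimated residual-disease probability with the truth
#' `P_true(K >= 1) = 1 - burden_law(0)`. Pipeline failures in individual
#' replicates are recorded, not fatal.
#'
#' @param cfg an `mpm_synth_config`.
#' @param n_replicates number of simulated cohorts (>= 1).
#' @param seed integer base seed; replicate `r` uses `seed + r * 100003`.
#' @param target_n completion target (default 13).
#' @param fit_method,lambda_reg passed to [mpm_fit()].
#' @return an object of class `mpm_recovery`: list with `estimates` (one row
#'   per replicate), `truth`, `mean_estimate`, `bias`, `rmse`, `n_failed`.
#' @export
recovery_experiment <- function(cfg, n_replicates, seed = 1L,
                                target_n = 13L, fit_method = "ls",
                                lambda_reg = 1e-8) {
  stopifnot(inherits(cfg, "mpm_synth_config"), n_replicates >= 1L)
  truth <- 1 - law_zero_mass(cfg$burden_law)
  H <- build_forward_matrix(cfg$n_subsurfaces, target_n)  # shared across reps
  est <- rep(NA_real_, n_replicates)
  err <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      cohort <- sample_cohort(cfg, seed = seed + r * 100003L)
      cohort <- complete_cohort(cohort, target_n)
      hist <- positive_count_histogram(cohort)
      pois <- switch(fit_method,
                     ls = fit_poisson_ls(hist),
                     mle = fit_poisson_mle(hist))
      burden <- invert_burden(pois, H, lambda_reg = lambda_reg)
      residual_probability(burden)
    }, error = function(e) e)
    if (inherits(res, "error")) err[r] <- conditionMessage(res) else est[r] <- res
  }
  ok <- !is.na(est)
  structure(list(
    estimates = data.frame(replicate = seq_len(n_replicates),
                           estimate = est, error = err,
                           stringsAsFactors = FALSE),
    truth = truth,
    mean_estimate = mean(est[ok]),
    bias = mean(est[ok]) - truth,
    rmse = sqrt(mean((est[ok] - truth)^2)),
    n_failed = sum(!ok)
  ), class = "mpm_recovery")
}

#' @export
print.mpm_recovery <- function(x, ...) {
  cat("<mpm_recovery> ", nrow(x$estimates), " replicates (",
      x$n_failed, " failed)\n", sep = "")
  cat(sprintf("  truth P(K >= 1) = %.4f\n", x$truth))
  cat(sprintf("  mean estimate   = %.4f  (bias %+.4f, RMSE %.4f)\n",
              x$mean_estimate, x$bias, x$rmse))
  invisible(x)
}
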