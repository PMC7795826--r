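#' Construct a biopsy cohort
#'
#' A cohort is a data frame with one row per patient: an identifier, the
#' number of peritoneal biopsies taken from macroscopically healthy
#' peritoneum, the number of those positive for microscopic peritoneal
#' metastases (mPM), and optional height/weight used for the body-surface-area
#' estimate of the peritoneal area.
#'
#' @param patient_id vector of unique patient identifiers.
#' @param n_biopsies_taken integer, biopsies taken per patient (1 to
#'   `max_biopsies`).
#' @param n_positive integer, biopsies positive for mPM (at most
#'   `n_biopsies_taken`).
#' @param height_cm,weight_kg optional body measurements; strictly positive
#'   where present.
#' @param max_biopsies largest admissible number of biopsies per patient
#'   (default 13, one per region of the Peritoneal Carcinomatosis Index).
#' @return an object of class `mpm_cohort` (a data frame) with attribute
#'   `completed = FALSE`.
#' @seealso [read_cohort()], [complete_cohort()], [prevalence()],
#'   [positive_count_histogram()]
#' @export
mpm_cohort <- function(patient_id, n_biopsies_taken, n_positive,
                       height_cm = NA_real_, weight_kg = NA_real_,
                       max_biopsies = 13L) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    n_biopsies_taken = as.integer(n_biopsies_taken),
    n_positive = as.integer(n_positive),
    height_cm = as.numeric(height_cm),
    weight_kg = as.numeric(weight_kg),
    stringsAsFactors = FALSE
  )
  validate_cohort(df, max_biopsies = max_biopsies)
  structure(df,
    class = c("mpm_cohort", "data.frame"),
    completed = FALSE, max_biopsies = as.integer(max_biopsies)
  )
}

validate_cohort <- function(df, max_biopsies = 13L) {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyDuplicated(df$patient_id)) {
    stop("duplicated patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  }
  bad <- which(is.na(df$n_biopsies_taken) | df$n_biopsies_taken < 1L |
                 df$n_biopsies_taken > max_biopsies)
  if (length(bad)) {
    stop("n_biopsies_taken outside 1..", max_biopsies, " for patient(s): ",
         paste(df$patient_id[bad], collapse = ", "))
  }
  bad <- which(is.na(df$n_positive) | df$n_positive < 0L |
                 df$n_positive > df$n_biopsies_taken)
  if (length(bad)) {
    stop("n_positive must satisfy 0 <= n_positive <= n_biopsies_taken; ",
         "violated for patient(s): ", paste(df$patient_id[bad], collapse = ", "))
  }
  for (col in c("height_cm", "weight_kg")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) {
      stop(col, " must be strictly positive; violated for patient(s): ",
           paste(df$patient_id[bad], collapse = ", "))
    }
  }
  invisible(df)
}

#' Read a cohort from a CSV file
#'
#' Expects a comma-separated file with a header row and columns `patient_id`,
#' `n_biopsies_taken`, `n_positive`, and optionally `height_cm`, `weight_kg`.
#' Extra columns are ignored with a warning. An empty file (header only)
#' yields a valid empty cohort.
#'
#' @param path path to the CSV file.
#' @param max_biopsies see [mpm_cohort()].
#' @return an `mpm_cohort` with `completed = FALSE`; row order preserved.
#' @export
read_cohort <- function(path, max_biopsies = 13L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("patient_id", "n_biopsies_taken", "n_positive")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  optional <- c("height_cm", "weight_kg")
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  for (col in optional) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  }
  df <- df[, c(required, optional)]
  if (nrow(df) == 0L) {
    message("cohort file ", path, " contains no patient rows")
    return(structure(
      data.frame(patient_id = character(), n_biopsies_taken = integer(),
                 n_positive = integer(), height_cm = numeric(),
                 weight_kg = numeric(), stringsAsFactors = FALSE),
      class = c("mpm_cohort", "data.frame"),
      completed = FALSE, max_biopsies = as.integer(max_biopsies)
    ))
  }
  mpm_cohort(df$patient_id, df$n_biopsies_taken, df$n_positive,
             df$height_cm, df$weight_kg, max_biopsies = max_biopsies)
}

#' Write a cohort to a CSV file
#'
#' @param cohort an `mpm_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mpm_cohort"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Complete a cohort to a uniform number of biopsies
#'
#' The inference model assumes the same number of biopsies for every patient.
#' Patients with fewer than `target_n` biopsies are padded with artificial
#' negative (mPM-absent) biopsies: `n_biopsies_taken` is raised to `target_n`
#' and `n_positive` is unchanged. Because padding can only add negatives, the
#' downstream residual-disease probability is, if anything, underestimated.
#'
#' @param cohort an `mpm_cohort`.
#' @param target_n uniform biopsy count after completion. Default `NULL` uses
#'   the cohort maximum; the reference analysis fixes 13.
#' @return the completed cohort (`completed = TRUE`).
#' @export
complete_cohort <- function(cohort, target_n = NULL) {
  stopifnot(inherits(cohort, "mpm_cohort"))
  if (is.null(target_n)) {
    if (nrow(cohort) == 0L) stop("cannot infer target_n from an empty cohort")
    target_n <- max(cohort$n_biopsies_taken)
  }
  target_n <- as.integer(target_n)
  over <- which(cohort$n_biopsies_taken > target_n)
  if (length(over)) {
    stop("n_biopsies_taken exceeds target_n = ", target_n,
         " for patient(s): ", paste(cohort$patient_id[over], collapse = ", "))
  }
  cohort$n_biopsies_taken <- rep.int(target_n, nrow(cohort))
  attr(cohort, "completed") <- TRUE
  attr(cohort, "max_biopsies") <- max(attr(cohort, "max_biopsies"), target_n)
  cohort
}

is_completed <- function(cohort) isTRUE(attr(cohort, "completed"))

#' Prevalence of detected microscopic disease
#'
#' Fraction of patients with at least one biopsy positive for mPM. This is a
#' lower bound on the true disease prevalence since biopsies sample a
#' negligible fraction of the peritoneum.
#'
#' @param cohort a non-empty `mpm_cohort`.
#' @return proportion in \[0, 1\].
#' @export
prevalence <- function(cohort) {
  stopifnot(inherits(cohort, "mpm_cohort"))
  if (nrow(cohort) == 0L) stop("prevalence is undefined for an empty cohort")
  mean(cohort$n_positive >= 1L)
}

#' Relative histogram of positive-biopsy counts
#'
#' Relative frequency of patients with 0, 1, ..., n positive biopsies, where
#' n is the (uniform) number of biopsies per patient. The cohort must have
#' been completed with [complete_cohort()] first.
#'
#' @param cohort a completed `mpm_cohort`.
#' @return an object of class `mpm_histogram`: list with `support`
#'   (integers `0:n`), `freq` (non-negative, sums to 1) and `n_patients`.
#' @export
positive_count_histogram <- function(cohort) {
  stopifnot(inherits(cohort, "mpm_cohort"))
  if (!is_completed(cohort)) {
    stop("cohort must be completed to a uniform number of biopsies first; ",
         "see complete_cohort()")
  }
  if (nrow(cohort) == 0L) stop("cannot build a histogram from an empty cohort")
  n <- cohort$n_biopsies_taken[1L]
  counts <- tabulate(cohort$n_positive + 1L, nbins = n + 1L)
  relative_histogram(0:n, counts / nrow(cohort), n_patients = nrow(cohort))
}

#' Construct a relative histogram directly
#'
#' @param support consecutive integers `0:n`.
#' @param freq relative frequencies over `support`; non-negative, summing
#'   to 1 within 1e-12.
#' @param n_patients optional number of patients behind the frequencies.
#' @return an `mpm_histogram`.
#' @export
relative_histogram <- function(support, freq, n_patients = NA_integer_) {
  support <- as.integer(support)
  if (!identical(support, 0:max(support))) {
    stop("support must be the consecutive integers 0:n")
  }
  if (length(freq) != length(support)) stop("freq and support lengths differ")
  if (any(freq < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freq) - 1) > 1e-12) stop("frequencies must sum to 1 (within 1e-12)")
  structure(list(support = support, freq = as.numeric(freq),
                 n_patients = n_patients),
            class = "mpm_histogram")
}

#' @export
print.mpm_cohort <- function(x, ...) {
  cat("<mpm_cohort> ", nrow(x), " patients",
      if (is_completed(x)) paste0(", completed to ", x$n_biopsies_taken[1L],
                                  " biopsies each") else "", "\n", sep = "")
  if (nrow(x) > 0L) {
    cat("  with mPM detected: ", sum(x$n_positive >= 1L),
        sprintf(" (%.1f%%)", 100 * prevalence(x)), "\n", sep = "")
  }
  NextMethod()
}

#' @export
print.mpm_histogram <- function(x, ...) {
  cat("<mpm_histogram> relative frequencies over 0..",
      max(x$support), " positive biopsies", sep = "")
  if (!is.na(x$n_patients)) cat(" (", x$n_patients, " patients)", sep = "")
  cat("\n")
  nz <- x$freq > 0
  print(stats::setNames(round(x$freq[nz], 4), x$support[nz]))
  invisible(x)
}

#' Packaged reference cohort
#'
#' The 26-patient ovarian-cancer cohort used throughout the documentation:
#' 19 patients with no positive biopsy, four with one, two with two and one
#' with seven, out of up to 13 biopsies of macroscopically healthy peritoneum
#' per patient. Per-patient biopsy totals and body measurements are synthetic
#' but match the published cohort summaries (median 7 biopsies, range 3-13;
#' mean body surface area about 1.65 m2).
#'
#' @return an `mpm_cohort` of 26 patients.
#' @export
mpm_example_cohort <- function() {
  path <- system.file("extdata", "ovarian_mpm_cohort_synthetic.csv",
                      package = "mpmburden", mustWork = TRUE)
  read_cohort(path)
}
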