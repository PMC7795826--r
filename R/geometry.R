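#' Body surface area from height and weight
#'
#' Standard clinical formulas. Du Bois:
#' `0.007184 * weight^0.425 * height^0.725`; Mosteller:
#' `sqrt(height * weight / 3600)`. Body surface area serves as a proxy for
#' the total peritoneal surface area.
#'
#' @param height_cm height in centimetres (> 0); vectorised.
#' @param weight_kg weight in kilograms (> 0); vectorised.
#' @param formula `"dubois"` (default) or `"mosteller"`.
#' @return body surface area in square metres.
#' @export
body_surface_area <- function(height_cm, weight_kg,
                              formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(!is.na(height_cm) & height_cm <= 0) ||
      any(!is.na(weight_kg) & weight_kg <= 0)) {
    stop("height_cm and weight_kg must be strictly positive")
  }
  switch(formula,
    dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
    mosteller = sqrt(height_cm * weight_kg / 3600)
  )
}

#' Peritoneal surface area from body surface area
#'
#' The peritoneal surface area is taken equal to the body surface area
#' (identity mapping); only the units change, from square metres to square
#' centimetres.
#'
#' @param bsa_m2 body surface area in m2 (> 0).
#' @return peritoneal surface area in cm2.
#' @export
peritoneal_area_from_bsa <- function(bsa_m2) {
  if (any(!is.na(bsa_m2) & bsa_m2 <= 0)) stop("bsa_m2 must be strictly positive")
  bsa_m2 * 1e4
}

#' Number of biopsy-sized sub-surfaces of the peritoneum
#'
#' Discretises the peritoneum into patches the size of one biopsy:
#' `N = round(peritoneal_area / biopsy_area)`. The reference configuration
#' (16,000 cm2 of peritoneum, 4 cm2 biopsies) gives N = 4000.
#'
#' @param peritoneal_area_cm2 total peritoneal area in cm2 (> 0).
#' @param biopsy_area_cm2 area sampled by one biopsy in cm2 (> 0; default 4).
#' @param rounding `"nearest"` (default), `"floor"` or `"ceiling"`, applied
#'   to the ratio.
#' @param pre_round optional rounding of the area itself before dividing,
#'   so the grid does not inherit spurious precision from the area estimate:
#'   `"none"` (default), `"signif2"` (two significant figures, e.g.
#'   16,500 -> 16,000) or `"nearest500"`.
#' @return integer N >= 1.
#' @export
subsurface_count <- function(peritoneal_area_cm2, biopsy_area_cm2 = 4,
                             rounding = c("nearest", "floor", "ceiling"),
                             pre_round = c("none", "signif2", "nearest500")) {
  rounding <- match.arg(rounding)
  pre_round <- match.arg(pre_round)
  if (peritoneal_area_cm2 <= 0 || biopsy_area_cm2 <= 0) {
    stop("areas must be strictly positive")
  }
  peritoneal_area_cm2 <- switch(pre_round,
    none = peritoneal_area_cm2,
    signif2 = signif(peritoneal_area_cm2, 2),
    nearest500 = round(peritoneal_area_cm2 / 500) * 500
  )
  ratio <- peritoneal_area_cm2 / biopsy_area_cm2
  n <- switch(rounding,
    nearest = round(ratio),
    floor = floor(ratio),
    ceiling = ceiling(ratio)
  )
  max(1L, as.integer(n))
}

#' Sub-surface grid
#'
#' Bundles the discretisation of the peritoneum: the number of sub-surfaces
#' N, the biopsy area, and the total peritoneal area they represent.
#'
#' @param n_subsurfaces integer N >= 1.
#' @param biopsy_area_cm2 area of one sub-surface in cm2.
#' @param peritoneal_area_cm2 total area; defaults to `N * biopsy_area`.
#' @return an object of class `mpm_grid`.
#' @export
subsurface_grid <- function(n_subsurfaces, biopsy_area_cm2 = 4,
                            peritoneal_area_cm2 = n_subsurfaces * biopsy_area_cm2) {
  n_subsurfaces <- as.integer(n_subsurfaces)
  if (n_subsurfaces < 1L) stop("n_subsurfaces must be >= 1")
  if (biopsy_area_cm2 <= 0 || peritoneal_area_cm2 <= 0) {
    stop("areas must be strictly positive")
  }
  structure(list(n_subsurfaces = n_subsurfaces,
                 biopsy_area_cm2 = biopsy_area_cm2,
                 peritoneal_area_cm2 = peritoneal_area_cm2),
            class = "mpm_grid")
}

#' @export
print.mpm_grid <- function(x, ...) {
  cat("<mpm_grid> N = ", x$n_subsurfaces, " sub-surfaces of ",
      x$biopsy_area_cm2, " cm2 (peritoneum ", x$peritoneal_area_cm2,
      " cm2)\n", sep = "")
  invisible(x)
}

#' Sub-surface grid estimated from a cohort
#'
#' Computes per-patient body surface areas where height and weight are
#' available, averages the implied peritoneal areas, pre-rounds the mean to
#' the nearest `area_rounding_cm2` (so that the reported grid does not carry
#' spurious precision), and divides by the biopsy area. Patients without
#' body measurements fall back to `default_peritoneal_area_cm2`.
#'
#' @param cohort an `mpm_cohort`.
#' @param biopsy_area_cm2 biopsy area in cm2 (default 4).
#' @param bsa_formula passed to [body_surface_area()].
#' @param default_peritoneal_area_cm2 fallback area for patients without
#'   height/weight (default 16,000 cm2).
#' @param area_rounding_cm2 rounding unit for the cohort mean area
#'   (default 500 cm2).
#' @return an `mpm_grid`.
#' @export
cohort_subsurface_grid <- function(cohort, biopsy_area_cm2 = 4,
                                   bsa_formula = "dubois",
                                   default_peritoneal_area_cm2 = 16000,
                                   area_rounding_cm2 = 500) {
  stopifnot(inherits(cohort, "mpm_cohort"))
  if (nrow(cohort) == 0L) {
    area <- default_peritoneal_area_cm2
  } else {
    bsa <- body_surface_area(cohort$height_cm, cohort$weight_kg,
                             formula = bsa_formula)
    per_patient <- ifelse(is.na(bsa), default_peritoneal_area_cm2,
                          peritoneal_area_from_bsa(bsa))
    area <- mean(per_patient)
  }
  area <- round(area / area_rounding_cm2) * area_rounding_cm2
  subsurface_grid(subsurface_count(area, biopsy_area_cm2),
                  biopsy_area_cm2 = biopsy_area_cm2,
                  peritoneal_area_cm2 = area)
}
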