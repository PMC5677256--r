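#' Regression coefficients of the full oilseed yield model
#'
#' The full model predicts oilseed yield (kg/ha) from root-zone (0-1.2 m)
#' boron, salinity, leaching fraction and gravimetric water content:
#' \deqn{Y = \beta_0 + \beta_1 B + \beta_2 B^2 + \beta_3 EC_e + \beta_4 EC_e^2
#'       + \beta_5 LF + \beta_6 \theta_g}
#' Defaults are the fitted coefficients for Ida Gold mustard on fine-textured
#' salt-affected soil, with applicability ranges equal to the min/max of the
#' trial data used to fit them.
#'
#' @param beta0,beta1,beta2,beta3,beta4,beta5,beta6 Numeric coefficients.
#'   `beta1`/`beta2` act on B (mg/L), `beta3`/`beta4` on EC_e (dS/m),
#'   `beta5` on LF and `beta6` on theta_g. Units are such that yield comes
#'   out in kg/ha.
#' @param ranges Named list of length-2 numeric vectors giving the inclusive
#'   applicability range of each regressor (`b`, `ece`, `lf`, `theta_g`).
#' @return An object of class `yield_coefficients`.
#' @export
#' @examples
#' yc <- yield_coefficients()
#' predict_yield_full(tibble::tibble(b = 4, ece = 6.8, lf = 0.27, theta_g = 0.19), yc)
yield_coefficients <- function(beta0 = 30.1, beta1 = 146.4, beta2 = -18.3,
                               beta3 = 83.0, beta4 = -6.1, beta5 = 1301.0,
                               beta6 = 319.8,
                               ranges = list(
                                 b = c(2.14, 24.24),
                                 ece = c(1.84, 29.97),
                                 lf = c(0.08, 0.61),
                                 theta_g = c(0.12, 0.25)
                               )) {
  stopifnot(is.numeric(beta0), is.numeric(beta1), is.numeric(beta2),
            is.numeric(beta3), is.numeric(beta4), is.numeric(beta5),
            is.numeric(beta6))
  if (beta2 >= 0 || beta4 >= 0) {
    stop("quadratic coefficients beta2 (B^2) and beta4 (EC_e^2) must be ",
         "negative for a concave yield response", call. = FALSE)
  }
  stopifnot(all(c("b", "ece", "lf", "theta_g") %in% names(ranges)))
  for (r in ranges) stopifnot(length(r) == 2, r[1] <= r[2])
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         beta4 = beta4, beta5 = beta5, beta6 = beta6, ranges = ranges),
    class = "yield_coefficients"
  )
}

#' Two-piece linear (Maas-Hoffman) salt tolerance parameters
#'
#' Relative yield is 100% up to the salinity threshold `a` and declines
#' linearly at `b` percent per dS/m beyond it. Defaults are the fitted values
#' for Ida Gold mustard oilseed (threshold 8.3 dS/m, slope 17%/dS/m).
#'
#' @param threshold_a Salinity threshold, dS/m (> 0).
#' @param slope_b Yield decrement beyond the threshold, % per dS/m (> 0).
#' @return An object of class `salt_tolerance`.
#' @export
salt_tolerance <- function(threshold_a = 8.3, slope_b = 17) {
  stopifnot(threshold_a > 0, slope_b > 0)
  structure(list(threshold_a = threshold_a, slope_b = slope_b),
            class = "salt_tolerance")
}

#' Three-piece linear boron tolerance parameters
#'
#' Relative yield is 100% inside the boron optimum
#' `[deficiency_threshold, toxicity_threshold]`, declines at
#' `deficiency_slope` below it and at `toxicity_slope` above it. The default
#' optimum is 4.2-8 mg/L with a 28%/(mg/L) toxicity decline; the deficiency
#' slope is not reported for this crop, so the default is the slope implied by
#' zero yield at B = 0 rising to 100% at 4.2 mg/L (100/4.2).
#'
#' @param deficiency_threshold,toxicity_threshold Boron optimum bounds, mg/L.
#' @param toxicity_slope,deficiency_slope Declines in % per mg/L (> 0).
#' @return An object of class `boron_tolerance`.
#' @export
boron_tolerance <- function(deficiency_threshold = 4.2, toxicity_threshold = 8,
                            toxicity_slope = 28,
                            deficiency_slope = 100 / 4.2) {
  stopifnot(deficiency_threshold < toxicity_threshold,
            toxicity_slope > 0, deficiency_slope > 0)
  structure(list(deficiency_threshold = deficiency_threshold,
                 toxicity_threshold = toxicity_threshold,
                 toxicity_slope = toxicity_slope,
                 deficiency_slope = deficiency_slope),
            class = "boron_tolerance")
}

#' Quadratic single-stressor tolerance parameters
#'
#' Yield (kg/ha) as a concave quadratic in one stressor:
#' `Y = c0 + c1 x + c2 x^2` with `c2 < 0`.
#' [quadratic_salt()] and [quadratic_boron()] return the fitted curves for
#' salinity (`74.0 + 254.6 EC_e - 18.8 EC_e^2`) and boron
#' (`-418.0 + 555.2 B - 42.4 B^2`).
#'
#' @param c0,c1,c2 Quadratic coefficients; `c2` must be negative.
#' @return An object of class `quadratic_tolerance`.
#' @export
quadratic_tolerance <- function(c0, c1, c2) {
  stopifnot(is.numeric(c0), is.numeric(c1), is.numeric(c2))
  if (c2 >= 0) stop("c2 must be negative (concave response)", call. = FALSE)
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "quadratic_tolerance")
}

#' @rdname quadratic_tolerance
#' @export
quadratic_salt <- function() quadratic_tolerance(74.0, 254.6, -18.8)

#' @rdname quadratic_tolerance
#' @export
quadratic_boron <- function() quadratic_tolerance(-418.0, 555.2, -42.4)

#' Oilseed-to-biofuel conversion parameters
#'
#' Oilseed mass converts to biofuel mass through the seed oil content and the
#' press extraction efficiency, and to volume through the litres-per-kg
#' factor. Defaults: 26% oil content, 64% extraction efficiency, and the
#' printed 175.3 L per 166.4 kg ratio (so 1000 kg/ha of oilseed yields
#' 166.4 kg/ha = 175.3 L/ha of biofuel).
#'
#' @param oil_content_fraction Oil mass fraction of the seed, in (0, 1].
#' @param extraction_efficiency Fraction of the oil recovered, in (0, 1].
#' @param liters_per_kg Biofuel volume per unit mass, L/kg (> 0).
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(oil_content_fraction = 0.26,
                              extraction_efficiency = 0.64,
                              liters_per_kg = 175.3 / 166.4) {
  stopifnot(oil_content_fraction > 0, oil_content_fraction <= 1,
            extraction_efficiency > 0, extraction_efficiency <= 1,
            liters_per_kg > 0)
  structure(list(oil_content_fraction = oil_content_fraction,
                 extraction_efficiency = extraction_efficiency,
                 liters_per_kg = liters_per_kg),
            class = "conversion_params")
}

#' @export
print.yield_coefficients <- function(x, ...) {
  cat("Full yield model coefficients (kg/ha):\n")
  cat(sprintf("  Y = %.1f + %.1f B %+.1f B^2 %+.1f ECe %+.1f ECe^2 %+.1f LF %+.1f theta_g\n",
              x$beta0, x$beta1, x$beta2, x$beta3, x$beta4, x$beta5, x$beta6))
  rng <- vapply(x$ranges, function(r) sprintf("[%g, %g]", r[1], r[2]), "")
  cat("  applicability:", paste(names(rng), rng, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.salt_tolerance <- function(x, ...) {
  cat(sprintf("Two-piece salt tolerance: threshold %.2f dS/m, slope %.2f %%/(dS/m)\n",
              x$threshold_a, x$slope_b))
  invisible(x)
}

#' @export
print.boron_tolerance <- function(x, ...) {
  cat(sprintf("Three-piece boron tolerance: optimum [%.2f, %.2f] mg/L, slopes %.2f / %.2f %%/(mg/L)\n",
              x$deficiency_threshold, x$toxicity_threshold,
              x$deficiency_slope, x$toxicity_slope))
  invisible(x)
}
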