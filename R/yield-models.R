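#' Predict oilseed yield from the full polynomial regression model
#'
#' Evaluates the full yield model
#' `Y = beta0 + beta1*B + beta2*B^2 + beta3*ECe + beta4*ECe^2 + beta5*LF +
#' beta6*theta_g` for each row of `data` and appends the prediction as
#' `yield_kg_ha`. Negative polynomial values are truncated to 0: the model is
#' an empirical fit and a field cannot produce negative seed mass.
#'
#' @param data A data frame with numeric columns `b` (boron, mg/L), `ece`
#'   (saturation-extract EC, dS/m), `lf` (leaching fraction) and `theta_g`
#'   (gravimetric water content, kg/kg). All four must be present and
#'   non-missing.
#' @param coeffs A [yield_coefficients()] object.
#' @return `data` as a tibble with an added `yield_kg_ha` column.
#' @export
#' @examples
#' predict_yield_full(
#'   tibble::tibble(b = 4.0, ece = 6.8, lf = 0.27, theta_g = 0.19)
#' )
predict_yield_full <- function(data, coeffs = yield_coefficients()) {
  stopifnot(is.data.frame(data), inherits(coeffs, "yield_coefficients"))
  needed <- c("b", "ece", "lf", "theta_g")
  missing_col <- setdiff(needed, names(data))
  if (length(missing_col) > 0) {
    stop("missing regressor column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) {
    if (anyNA(data[[col]])) {
      stop("missing value(s) in regressor '", col, "'", call. = FALSE)
    }
  }
  data <- tibble::as_tibble(data)
  data$yield_kg_ha <- yield_polynomial(data$b, data$ece, data$lf,
                                       data$theta_g, coeffs)
  data
}

# raw polynomial, truncated at 0; vectorised over all inputs
yield_polynomial <- function(b, ece, lf, theta_g, coeffs) {
  y <- coeffs$beta0 + coeffs$beta1 * b + coeffs$beta2 * b^2 +
    coeffs$beta3 * ece + coeffs$beta4 * ece^2 +
    coeffs$beta5 * lf + coeffs$beta6 * theta_g
  pmax(y, 0)
}

#' Relative yield under the two-piece linear salt tolerance model
#'
#' 100% up to the salinity threshold, then a linear decline of `slope_b`
#' percent per dS/m, floored at 0.
#'
#' @param ece Root-zone salinity, dS/m (vectorised, non-negative).
#' @param params A [salt_tolerance()] object.
#' @return Relative yield in percent, in \[0, 100\].
#' @export
#' @examples
#' relative_yield_salt(c(5, 9.3, 20))
relative_yield_salt <- function(ece, params = salt_tolerance()) {
  stopifnot(inherits(params, "salt_tolerance"), all(ece >= 0, na.rm = TRUE))
  yr <- ifelse(ece <= params$threshold_a, 100,
               100 - params$slope_b * (ece - params$threshold_a))
  pmin(pmax(yr, 0), 100)
}

#' Relative yield under the three-piece linear boron tolerance model
#'
#' 100% inside the boron optimum, a linear decline on the deficiency side
#' below it and on the toxicity side above it, floored at 0.
#'
#' @param b Boron concentration, mg/L (vectorised, non-negative).
#' @param params A [boron_tolerance()] object.
#' @return Relative yield in percent, in \[0, 100\].
#' @export
#' @examples
#' relative_yield_boron(c(6, 9, 11.6))
relative_yield_boron <- function(b, params = boron_tolerance()) {
  stopifnot(inherits(params, "boron_tolerance"), all(b >= 0, na.rm = TRUE))
  yr <- dplyr::case_when(
    b < params$deficiency_threshold ~
      100 - params$deficiency_slope * (params$deficiency_threshold - b),
    b > params$toxicity_threshold ~
      100 - params$toxicity_slope * (b - params$toxicity_threshold),
    TRUE ~ 100
  )
  pmin(pmax(yr, 0), 100)
}

#' Yield from a quadratic single-stressor tolerance model
#'
#' Evaluates `c0 + c1*x + c2*x^2`, floored at 0.
#'
#' @param x Stressor value (vectorised, non-negative).
#' @param params A [quadratic_tolerance()] object.
#' @return Yield, kg/ha.
#' @export
predict_yield_quadratic <- function(x, params) {
  stopifnot(inherits(params, "quadratic_tolerance"), all(x >= 0, na.rm = TRUE))
  pmax(params$c0 + params$c1 * x + params$c2 * x^2, 0)
}

#' Stressor value maximizing a concave quadratic response
#'
#' The vertex of `c0 + c1*x + c2*x^2`, i.e. `-c1 / (2 c2)` — the stressor
#' level at which the first derivative of the fitted response is zero.
#' Accepts either a [quadratic_tolerance()] object or a (linear, quadratic)
#' coefficient pair, e.g. the B or EC_e pair of the full model.
#'
#' @param params A [quadratic_tolerance()] object, or a numeric vector
#'   `c(linear, quadratic)`.
#' @return The stressor value at maximum yield.
#' @export
#' @examples
#' argmax_quadratic(c(83.0, -6.1))   # ECe of maximum yield in the full model
#' argmax_quadratic(quadratic_salt())
argmax_quadratic <- function(params) {
  if (inherits(params, "quadratic_tolerance")) {
    c1 <- params$c1
    c2 <- params$c2
  } else {
    stopifnot(is.numeric(params), length(params) == 2)
    c1 <- params[1]
    c2 <- params[2]
  }
  if (c2 >= 0) {
    stop("quadratic coefficient must be negative: no interior maximum",
         call. = FALSE)
  }
  -c1 / (2 * c2)
}

#' Stressor value at which a piecewise tolerance model reaches zero yield
#'
#' For the two-piece salt model this is `a + 100/b`; for the three-piece
#' boron model it is the toxicity-side zero,
#' `toxicity_threshold + 100/toxicity_slope`.
#'
#' @param params A [salt_tolerance()] or [boron_tolerance()] object.
#' @return The stressor value where relative yield first reaches 0.
#' @export
#' @examples
#' zero_yield_threshold(salt_tolerance())   # 8.3 + 100/17
#' zero_yield_threshold(boron_tolerance())  # 8 + 100/28
zero_yield_threshold <- function(params) {
  if (inherits(params, "salt_tolerance")) {
    params$threshold_a + 100 / params$slope_b
  } else if (inherits(params, "boron_tolerance")) {
    params$toxicity_threshold + 100 / params$toxicity_slope
  } else {
    stop("params must be a salt_tolerance or boron_tolerance object",
         call. = FALSE)
  }
}

model_choice_levels <- c("FULL_MODEL", "TOLERANCE_MOST_LIMITING",
                         "SALT_TOLERANCE_ONLY", "OPTIMAL")

#' Choose the yield model for each field from data availability
#'
#' The full polynomial model is only trusted where a complete set of inputs
#' exists, every input lies inside the range of the data used to fit it, and
#' the soil is fine-textured (the model was developed on a fine-textured
#' field). Otherwise the piecewise tolerance models step in:
#'
#' * `FULL_MODEL`: all of `b`, `ece`, `lf`, `theta_g` present, all inside
#'   the applicability ranges, texture not coarse.
#' * `TOLERANCE_MOST_LIMITING`: boron information available but the full
#'   model is not applicable (incomplete set, out-of-range value, or coarse
#'   texture); salt and boron tolerance are evaluated and the more limiting
#'   (smaller relative yield) governs.
#' * `SALT_TOLERANCE_ONLY`: only salinity is available.
#' * `OPTIMAL`: neither salinity nor boron available; all properties are
#'   assumed non-limiting.
#'
#' @param data A data frame with (possibly `NA`) columns `b`, `ece`, `lf`,
#'   `theta_g`, and optionally `texture` (`"fine"` or `"coarse"`; missing
#'   column means fine).
#' @param coeffs A [yield_coefficients()] object supplying the ranges.
#' @return `data` as a tibble with an added factor column `model_choice`.
#' @export
select_model <- function(data, coeffs = yield_coefficients()) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  get_col <- function(col) {
    if (col %in% names(data)) data[[col]] else rep(NA_real_, n)
  }
  b <- get_col("b")
  ece <- get_col("ece")
  lf <- get_col("lf")
  theta_g <- get_col("theta_g")
  texture <- if ("texture" %in% names(data)) data$texture else rep("fine", n)

  in_rng <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  full_ok <- in_rng(b, coeffs$ranges$b) &
    in_rng(ece, coeffs$ranges$ece) &
    in_rng(lf, coeffs$ranges$lf) &
    in_rng(theta_g, coeffs$ranges$theta_g) &
    texture != "coarse"

  choice <- dplyr::case_when(
    full_ok ~ "FULL_MODEL",
    !is.na(b) ~ "TOLERANCE_MOST_LIMITING",
    !is.na(ece) ~ "SALT_TOLERANCE_ONLY",
    TRUE ~ "OPTIMAL"
  )
  data$model_choice <- factor(choice, levels = model_choice_levels)
  data
}

#' Predict field yield through the model-selection hierarchy
#'
#' Applies, per row, the model chosen by [select_model()] (or a
#' pre-computed `model_choice` column): the full polynomial where
#' applicable, the most-limiting of the salt and boron tolerance models
#' where boron data exist, salt tolerance alone where only salinity is
#' known, and the unstressed plateau yield `y_max` where nothing is known.
#' Tolerance models return relative yield, scaled to absolute yield by
#' `y_max`. With `curve_family = "quadratic"` the quadratic salinity and
#' boron curves replace the piecewise ones under the same most-limiting
#' (minimum) rule, in absolute kg/ha.
#'
#' @param data A data frame of field inputs (`b`, `ece`, `lf`, `theta_g`,
#'   optional `texture`, optional precomputed `model_choice`).
#' @param coeffs A [yield_coefficients()] object.
#' @param salt_params A [salt_tolerance()] object.
#' @param boron_params A [boron_tolerance()] object.
#' @param y_max Plateau (unstressed) yield, kg/ha, used to scale relative
#'   yields. Defaults to 936, the vertex yield of the quadratic salinity
#'   tolerance curve.
#' @param curve_family `"piecewise"` (default) or `"quadratic"`.
#' @param quad_salt,quad_boron Quadratic curves used when
#'   `curve_family = "quadratic"`.
#' @return `data` as a tibble with `model_choice` and `yield_kg_ha` columns.
#' @export
predict_field_yield <- function(data, coeffs = yield_coefficients(),
                                salt_params = salt_tolerance(),
                                boron_params = boron_tolerance(),
                                y_max = 936,
                                curve_family = c("piecewise", "quadratic"),
                                quad_salt = quadratic_salt(),
                                quad_boron = quadratic_boron()) {
  curve_family <- match.arg(curve_family)
  stopifnot(y_max > 0)
  if (!"model_choice" %in% names(data)) data <- select_model(data, coeffs)
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  get_col <- function(col) {
    if (col %in% names(data)) data[[col]] else rep(NA_real_, n)
  }
  b <- get_col("b")
  ece <- get_col("ece")
  lf <- get_col("lf")
  theta_g <- get_col("theta_g")
  choice <- as.character(data$model_choice)

  full_rows <- choice == "FULL_MODEL"
  if (any(full_rows & (is.na(b) | is.na(ece) | is.na(lf) | is.na(theta_g)))) {
    stop("FULL_MODEL chosen for a row with a missing regressor", call. = FALSE)
  }

  # a missing stressor never limits: its relative yield is taken as 100%
  if (curve_family == "piecewise") {
    rel_salt <- ifelse(is.na(ece), 100, relative_yield_salt(pmax(ece, 0), salt_params))
    rel_b <- ifelse(is.na(b), 100, relative_yield_boron(pmax(b, 0), boron_params))
    tol_yield <- y_max * pmin(rel_salt, rel_b) / 100
    salt_only_yield <- y_max * rel_salt / 100
  } else {
    abs_salt <- ifelse(is.na(ece), y_max,
                       predict_yield_quadratic(pmax(ece, 0), quad_salt))
    abs_b <- ifelse(is.na(b), y_max,
                    predict_yield_quadratic(pmax(b, 0), quad_boron))
    tol_yield <- pmin(abs_salt, abs_b)
    salt_only_yield <- abs_salt
  }

  full_yield <- rep(NA_real_, n)
  if (any(full_rows)) {
    full_yield[full_rows] <- yield_polynomial(b[full_rows], ece[full_rows],
                                              lf[full_rows], theta_g[full_rows],
                                              coeffs)
  }

  data$yield_kg_ha <- dplyr::case_when(
    choice == "FULL_MODEL" ~ full_yield,
    choice == "TOLERANCE_MOST_LIMITING" ~ tol_yield,
    choice == "SALT_TOLERANCE_ONLY" ~ salt_only_yield,
    choice == "OPTIMAL" ~ y_max
  )
  data
}

#' One-standard-deviation sensitivity analysis of the full yield model
#'
#' Evaluates the full model at a baseline profile, then shifts each
#' regressor in turn by +1 standard deviation (others held at baseline) and
#' reports yield, the converted biofuel volume, and the percent change from
#' baseline. Default baseline: B and EC_e at their points of maximum yield
#' (4.0 mg/L, 6.8 dS/m), LF and theta_g at their trial means (0.27, 0.19);
#' default SDs are the trial standard deviations (B 6.06, EC_e 6.29,
#' LF 0.15, theta_g 0.05). Shifted values are used unrounded.
#'
#' @param coeffs A [yield_coefficients()] object.
#' @param baseline Named numeric vector `c(b=, ece=, lf=, theta_g=)`.
#' @param sds Named numeric vector of per-regressor standard deviations.
#' @param conversion A [conversion_params()] object.
#' @return A tibble with columns `scenario`, `yield_kg_ha`, `biofuel_L_ha`,
#'   `pct_change`, `b`, `ece`, `lf`, `theta_g`; one baseline row plus one
#'   row per shifted regressor.
#' @export
#' @examples
#' sensitivity_analysis()
sensitivity_analysis <- function(coeffs = yield_coefficients(),
                                 baseline = c(b = 4.0, ece = 6.8,
                                              lf = 0.27, theta_g = 0.19),
                                 sds = c(b = 6.06, ece = 6.29,
                                         lf = 0.15, theta_g = 0.05),
                                 conversion = conversion_params()) {
  vars <- c("b", "ece", "lf", "theta_g")
  stopifnot(all(vars %in% names(baseline)), all(vars %in% names(sds)))
  labels <- c(b = "B + 1 SD", ece = "ECe + 1 SD", lf = "LF + 1 SD",
              theta_g = "theta_g + 1 SD")
  profiles <- dplyr::bind_rows(
    tibble::as_tibble_row(baseline[vars]),
    purrr::map_dfr(vars, function(v) {
      p <- baseline[vars]
      p[v] <- p[v] + sds[v]
      tibble::as_tibble_row(p)
    })
  )
  profiles$scenario <- c("Baseline", unname(labels[vars]))
  out <- predict_yield_full(profiles, coeffs)
  out$biofuel_L_ha <- biofuel_mass_to_volume(
    oilseed_to_biofuel_mass(out$yield_kg_ha, conversion), conversion
  )
  base_yield <- out$yield_kg_ha[1]
  out$pct_change <- c(NA_real_,
                      100 * (out$yield_kg_ha[-1] - base_yield) / base_yield)
  out[, c("scenario", "yield_kg_ha", "biofuel_L_ha", "pct_change",
          "b", "ece", "lf", "theta_g")]
}
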