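#' Generate a synthetic oilseed field trial
#'
#' Emulates a salinity-gradient field trial: sites on a jittered grid,
#' root-zone edaphic values drawn from lognormal marginals matched to
#' configured means and SDs, and oilseed yield generated from the full
#' polynomial model plus Gaussian noise (truncated at 0). A configured
#' number of sites is forced to zero yield; these are placed at the
#' highest generated salinities, where a real trial loses its stand.
#' Nuisance covariates (pH_e, SP, SAR) with no effect on yield are
#' included for screening tests.
#'
#' Defaults reproduce the marginal statistics of the 0-1.2 m composite
#' trial data (EC_e 9.97/6.29 dS/m, B 10.03/6.06 mg/L, LF 0.27/0.15,
#' theta_g 0.19/0.05) on a 40-site design with 6 zero-yield sites.
#'
#' @param n_sites Number of sites (>= 8).
#' @param n_zero_yield Number of zero-yield sites (< `n_sites`).
#' @param means,sds Named numeric vectors (`ece`, `b`, `lf`, `theta_g`) of
#'   marginal targets on the natural scale.
#' @param noise_sd Yield noise SD, kg/ha.
#' @param coeffs Generating [yield_coefficients()].
#' @param marginals `"lognormal"` (default) or `"normal"` marginals
#'   (normal draws are truncated below at a small positive value).
#' @param field_side_m Side length of the square field, metres.
#' @param seed Random seed.
#' @return A tibble with columns `site_id`, `x_m`, `y_m`, `yield_kg_ha`,
#'   `ece`, `b`, `lf`, `theta_g`, `ph_e`, `sp`, `sar`, `zero_yield`.
#' @export
generate_trial <- function(n_sites = 40, n_zero_yield = 6,
                           means = c(ece = 9.97, b = 10.03, lf = 0.27,
                                     theta_g = 0.19),
                           sds = c(ece = 6.29, b = 6.06, lf = 0.15,
                                   theta_g = 0.05),
                           noise_sd = 100,
                           coeffs = yield_coefficients(),
                           marginals = c("lognormal", "normal"),
                           field_side_m = 400, seed = 1) {
  marginals <- match.arg(marginals)
  stopifnot(n_sites >= 8, n_zero_yield >= 0, n_zero_yield < n_sites,
            all(c("ece", "b", "lf", "theta_g") %in% names(means)),
            all(c("ece", "b", "lf", "theta_g") %in% names(sds)),
            noise_sd >= 0)
  set.seed(seed)
  side <- ceiling(sqrt(n_sites))
  grid <- expand.grid(gx = seq_len(side), gy = seq_len(side))[seq_len(n_sites), ]
  cell <- field_side_m / side
  x_m <- (grid$gx - 0.5) * cell + stats::runif(n_sites, -cell / 4, cell / 4)
  y_m <- (grid$gy - 0.5) * cell + stats::runif(n_sites, -cell / 4, cell / 4)

  draw <- function(m, s) {
    if (s == 0) return(rep(m, n_sites))
    if (marginals == "lognormal") {
      rlnorm_matched(n_sites, m, s)
    } else {
      pmax(stats::rnorm(n_sites, m, s), 1e-6)
    }
  }
  ece <- draw(means["ece"], sds["ece"])
  b <- draw(means["b"], sds["b"])
  lf <- pmin(draw(means["lf"], sds["lf"]), 1)
  theta_g <- pmin(draw(means["theta_g"], sds["theta_g"]), 1)
  ph_e <- stats::rnorm(n_sites, 7.74, 0.33)
  sp <- stats::rnorm(n_sites, 53.23, 4.01)
  sar <- rlnorm_matched(n_sites, 12.06, 4.02)

  yield <- yield_polynomial(b, ece, lf, theta_g, coeffs)
  if (noise_sd > 0) {
    yield <- pmax(yield + stats::rnorm(n_sites, 0, noise_sd), 0)
  }
  zero <- rep(FALSE, n_sites)
  if (n_zero_yield > 0) {
    zero[order(ece, decreasing = TRUE)[seq_len(n_zero_yield)]] <- TRUE
    yield[zero] <- 0
  }
  tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    x_m = x_m, y_m = y_m, yield_kg_ha = yield,
    ece = ece, b = b, lf = lf, theta_g = theta_g,
    ph_e = ph_e, sp = sp, sar = sar, zero_yield = zero
  )
}

# default salinity-category mixture: proportional to the residual-table
# data counts in the salt-affected categories (>= 4 dS/m)
default_category_weights <- function(table = residual_table()) {
  tb <- table[!is.na(table$lower) & table$lower >= 4, ]
  stats::setNames(tb$count / sum(tb$count), tb$lower)
}

#' Generate a synthetic salt-affected region
#'
#' Emulates the regional field database the Monte Carlo engine consumes:
#' fields with areas drawn from a lognormal distribution and rescaled to a
#' configured regional total, predicted mean root-zone salinities drawn
#' uniformly within salinity categories sampled from a mixture over the
#' residual-table bins, texture and land-cover flags assigned by configured
#' fractions, and default input-PDF parameters attached per field.
#'
#' The default region is a 1/100-scale stand-in for the study region
#' (1000 fields, 9,700 ha against the real 9.7e5 ha of salt-affected
#' soils); the full-scale region's salinity raster is not available.
#'
#' @param n_fields Number of fields.
#' @param total_area_ha Regional area, ha.
#' @param category_weights Named mixture weights over salinity-category
#'   lower bounds (summing to 1); default proportional to the residual
#'   table's salt-affected data counts.
#' @param frac_coarse Fraction of coarse-textured fields.
#' @param frac_orchard_vineyard Fraction of orchard/vineyard fields (split
#'   evenly between the two).
#' @param pdfs An [input_pdfs()] object whose parameters are attached to
#'   every field.
#' @param area_cv Coefficient of variation of field areas.
#' @param top_category_width Width (dS/m) of the open-ended top salinity
#'   category when sampling within it.
#' @param seed Random seed.
#' @return A tibble of field records with columns `field_id`, `area_ha`,
#'   `ece_pred_dsm`, `texture`, `landcover`, and per-field PDF parameter
#'   columns.
#' @export
generate_region <- function(n_fields = 1000, total_area_ha = 9700,
                            category_weights = default_category_weights(),
                            frac_coarse = 0.25,
                            frac_orchard_vineyard = 0.10,
                            pdfs = input_pdfs(), area_cv = 1,
                            top_category_width = 4, seed = 1) {
  stopifnot(n_fields >= 1, total_area_ha > 0,
            abs(sum(category_weights) - 1) < 1e-8,
            frac_coarse >= 0, frac_coarse <= 1,
            frac_orchard_vineyard >= 0, frac_orchard_vineyard <= 1)
  set.seed(seed)
  lowers <- as.numeric(names(category_weights))
  top <- max(lowers)
  # sample.int over indices: sample() misreads a length-1 numeric vector
  cat_draw <- lowers[sample.int(length(lowers), n_fields, replace = TRUE,
                                prob = category_weights)]
  width <- ifelse(cat_draw == top, top_category_width, 1)
  ece_pred <- cat_draw + stats::runif(n_fields) * width

  area <- rlnorm_matched(n_fields, 1, area_cv)
  area <- area / sum(area) * total_area_ha

  texture <- ifelse(stats::runif(n_fields) < frac_coarse, "coarse", "fine")
  u <- stats::runif(n_fields)
  landcover <- dplyr::case_when(
    u < frac_orchard_vineyard / 2 ~ "orchard",
    u < frac_orchard_vineyard ~ "vineyard",
    TRUE ~ "cropland"
  )
  tibble::tibble(
    field_id = sprintf("F%05d", seq_len(n_fields)),
    area_ha = area,
    ece_pred_dsm = ece_pred,
    texture = texture,
    landcover = landcover,
    b_mean = pdfs$b$mean, b_sd = pdfs$b$sd,
    lf_mean = pdfs$lf$mean, lf_sd = pdfs$lf$sd,
    theta_mean = pdfs$theta_g$mean, theta_sd = pdfs$theta_g$sd
  )
}

# expected salt-tolerance-only yield (kg/ha) for one predicted ECe under a
# normal residual PDF, by numerical quadrature
expected_salt_only_yield <- function(pred, mu, sd, salt_params, y_max) {
  if (sd == 0) {
    return(y_max * relative_yield_salt(max(pred - mu, 0), salt_params) / 100)
  }
  f <- function(r) {
    stats::dnorm(r, mu, sd) *
      y_max * relative_yield_salt(pmax(pred - r, 0), salt_params) / 100
  }
  stats::integrate(f, mu - 10 * sd, mu + 10 * sd, rel.tol = 1e-9)$value
}

#' Generate a calibration region with analytically known mean production
#'
#' Builds a salt-tolerance-only region (no boron data, so the model
#' hierarchy reduces to the salinity tolerance curve) whose expected
#' regional production is computable by quadrature: each field's expected
#' yield is an integral over its salinity residual PDF, and the regional
#' expectation follows by linearity of the area-weighted total. Field
#' areas are scaled so the expected production equals the mean of a target
#' shifted-gamma law, giving an end-to-end oracle for the Monte Carlo
#' engine that does not reuse the engine itself.
#'
#' @param target_fit A [shifted_gamma()] whose analytic mean the region's
#'   expected production matches.
#' @param n_fields Number of fields.
#' @param table A [residual_table()] (its whole-data-set row drives the
#'   salinity uncertainty).
#' @param salt_params A [salt_tolerance()] object.
#' @param y_max Plateau yield, kg/ha.
#' @param conversion A [conversion_params()] object.
#' @param degenerate If `TRUE`, the salinity residual SD is set to 0 and
#'   the expected production is exact (deterministic pipeline).
#' @param seed Random seed.
#' @return A list with `fields` (tibble, including `has_b = FALSE`),
#'   `expected_mean_q` (ML/yr) and `table` (the residual table used).
#' @export
generate_gamma_reference_region <- function(target_fit = shifted_gamma(),
                                            n_fields = 100,
                                            table = residual_table(),
                                            salt_params = salt_tolerance(),
                                            y_max = 936,
                                            conversion = conversion_params(),
                                            degenerate = FALSE, seed = 1) {
  stopifnot(inherits(target_fit, "shifted_gamma"), n_fields >= 1)
  set.seed(seed)
  ds <- which(is.na(table$lower))
  mu <- table$mean_residual[ds]
  sd <- if (degenerate) 0 else table$sd_residual[ds]
  if (degenerate) {
    tb <- table
    tb$sd_residual <- 0
    table <- residual_table(tb)
  }
  pred <- stats::runif(n_fields, 4, 12)
  area <- rlnorm_matched(n_fields, 1, 0.5)

  e_yield <- vapply(pred, expected_salt_only_yield, numeric(1),
                    mu = mu, sd = sd, salt_params = salt_params,
                    y_max = y_max)
  vol_per_ha <- biofuel_mass_to_volume(
    oilseed_to_biofuel_mass(e_yield, conversion), conversion)
  target_mean <- gamma_moments(target_fit)$mean
  scale_factor <- target_mean * 1e6 / sum(vol_per_ha * area)
  area <- area * scale_factor

  fields <- tibble::tibble(
    field_id = sprintf("G%05d", seq_len(n_fields)),
    area_ha = area,
    ece_pred_dsm = pred,
    texture = "fine",
    landcover = "cropland",
    has_b = FALSE, has_lf = FALSE, has_theta = FALSE
  )
  list(fields = fields, expected_mean_q = target_mean, table = table)
}
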