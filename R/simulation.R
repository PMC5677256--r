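#' Monte Carlo simulation configuration
#'
#' @param n_iterations Number of Monte Carlo iterations (default 10,000).
#' @param seed Master random seed; per-field, per-variable sub-streams are
#'   derived from it so that adding or removing a field does not perturb
#'   the draws of the others.
#' @param target_ml Production target, ML/yr (default 115).
#' @param curve_family `"piecewise"` or `"quadratic"` tolerance curves.
#' @param residual_mode `"dataset"` or `"category"` salinity residual PDF.
#' @param y_max Plateau yield used to scale relative tolerance yields,
#'   kg/ha.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_iterations = 10000, seed = 1,
                              target_ml = 115,
                              curve_family = c("piecewise", "quadratic"),
                              residual_mode = c("dataset", "category"),
                              y_max = 936) {
  stopifnot(n_iterations >= 1, target_ml > 0, y_max > 0)
  structure(list(
    n_iterations = as.integer(n_iterations),
    seed = as.integer(seed),
    target_ml = target_ml,
    curve_family = match.arg(curve_family),
    residual_mode = match.arg(residual_mode),
    y_max = y_max
  ), class = "simulation_config")
}

#' Convert oilseed mass to biofuel mass
#'
#' `biofuel = oilseed * oil_content * extraction_efficiency`; with defaults,
#' 1000 kg/ha of oilseed gives 166.4 kg/ha of biofuel.
#'
#' @param oilseed_kg_ha Oilseed yield, kg/ha (vectorised, non-negative).
#' @param params A [conversion_params()] object.
#' @return Biofuel mass, kg/ha.
#' @export
oilseed_to_biofuel_mass <- function(oilseed_kg_ha,
                                    params = conversion_params()) {
  stopifnot(all(oilseed_kg_ha >= 0, na.rm = TRUE))
  oilseed_kg_ha * params$oil_content_fraction * params$extraction_efficiency
}

#' Convert biofuel mass to volume
#'
#' With defaults, 166.4 kg/ha corresponds to 175.3 L/ha.
#'
#' @param mass_kg_ha Biofuel mass, kg/ha (vectorised, non-negative).
#' @param params A [conversion_params()] object.
#' @return Biofuel volume, L/ha.
#' @export
biofuel_mass_to_volume <- function(mass_kg_ha, params = conversion_params()) {
  stopifnot(all(mass_kg_ha >= 0, na.rm = TRUE))
  mass_kg_ha * params$liters_per_kg
}

#' Aggregate per-field yields to a regional biofuel total
#'
#' @param yields_kg_ha Per-field oilseed yields, kg/ha.
#' @param areas_ha Per-field areas, ha (same length).
#' @param params A [conversion_params()] object.
#' @return Regional biofuel production Q, ML/yr (1 ML = 1e6 L).
#' @export
regional_total <- function(yields_kg_ha, areas_ha,
                           params = conversion_params()) {
  if (length(yields_kg_ha) != length(areas_ha)) {
    stop("yields and areas must have the same length", call. = FALSE)
  }
  vol <- biofuel_mass_to_volume(oilseed_to_biofuel_mass(yields_kg_ha, params),
                                params)
  sum(vol * areas_ha) / 1e6
}

# deterministic 31-bit sub-stream seed from the master seed and a label
substream_seed <- function(seed, label) {
  h <- 5381
  for (c in utf8ToInt(label)) h <- (h * 33 + c) %% 2147483647
  s <- as.numeric(seed) %% 2147483647
  as.integer((h + s * 48271) %% 2147483647)
}

# logical availability column, defaulting to TRUE
avail_col <- function(fields, col) {
  if (col %in% names(fields)) {
    v <- fields[[col]]
    ifelse(is.na(v), TRUE, as.logical(v))
  } else {
    rep(TRUE, nrow(fields))
  }
}

#' Run the regional Monte Carlo biofuel production simulation
#'
#' For each iteration and each retained field, an observed salinity is
#' sampled from the field's predicted EC_e and the residual PDF, boron,
#' leaching fraction and water content are drawn from their lognormal
#' input PDFs, the yield model hierarchy picks and evaluates a model, the
#' yield is converted to biofuel volume, and the area-weighted regional
#' total Q (ML/yr) is accumulated. Draws use per-field, per-variable random
#' sub-streams derived from the master seed, so results are reproducible
#' and fields are statistically independent of each other's presence.
#'
#' @param fields A data frame of field records, already filtered with
#'   [filter_salt_affected()]: columns `field_id`, `area_ha`,
#'   `ece_pred_dsm`, optional `texture`, optional per-field PDF parameter
#'   columns, optional logical availability columns `has_b`, `has_lf`,
#'   `has_theta` (missing means available).
#' @param config A [simulation_config()].
#' @param table A [residual_table()].
#' @param pdfs An [input_pdfs()] object of default input PDFs.
#' @param coeffs,salt_params,boron_params Yield-model parameters.
#' @param conversion A [conversion_params()] object.
#' @return An object of class `saltoil_simulation` with elements `draws`
#'   (tibble of `iteration`, `Q_ML`), `summary` (one-row tibble: mean,
#'   median, sd, skewness, non-excess kurtosis), and `config`.
#' @export
run_simulation <- function(fields, config = simulation_config(),
                           table = residual_table(), pdfs = input_pdfs(),
                           coeffs = yield_coefficients(),
                           salt_params = salt_tolerance(),
                           boron_params = boron_tolerance(),
                           conversion = conversion_params()) {
  stopifnot(is.data.frame(fields), inherits(config, "simulation_config"))
  if (nrow(fields) == 0) stop("empty region: no fields to simulate",
                              call. = FALSE)
  stopifnot(all(c("field_id", "area_ha", "ece_pred_dsm") %in% names(fields)))
  stopifnot(all(fields$area_ha > 0), all(fields$ece_pred_dsm >= 0))
  fields <- tibble::as_tibble(fields)
  n_it <- config$n_iterations
  n_f <- nrow(fields)
  quad <- config$curve_family == "quadratic"
  qs <- quadratic_salt()
  qb <- quadratic_boron()

  has_b <- avail_col(fields, "has_b")
  has_lf <- avail_col(fields, "has_lf")
  has_theta <- avail_col(fields, "has_theta")
  texture <- if ("texture" %in% names(fields)) fields$texture else
    rep("fine", n_f)

  ds_row <- which(is.na(table$lower))
  col_or <- function(col, default) {
    if (col %in% names(fields)) ifelse(is.na(fields[[col]]), default,
                                       fields[[col]])
    else rep(default, n_f)
  }
  b_mean <- col_or("b_mean", pdfs$b$mean)
  b_sd <- col_or("b_sd", pdfs$b$sd)
  lf_mean <- col_or("lf_mean", pdfs$lf$mean)
  lf_sd <- col_or("lf_sd", pdfs$lf$sd)
  th_mean <- col_or("theta_mean", pdfs$theta_g$mean)
  th_sd <- col_or("theta_sd", pdfs$theta_g$sd)
  bnd <- function(min_col, max_col, def) {
    lo <- col_or(min_col, if (is.null(def)) -Inf else def[1])
    hi <- col_or(max_col, if (is.null(def)) Inf else def[2])
    if (any(hi < lo)) stop("infeasible bounds: max < min", call. = FALSE)
    list(lo = lo, hi = hi)
  }
  b_bnd <- bnd("b_min", "b_max", pdfs$b$bounds)
  th_bnd <- bnd("theta_min", "theta_max", pdfs$theta_g$bounds)

  rng <- coeffs$ranges
  Q <- numeric(n_it)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)

  for (i in seq_len(n_f)) {
    fid <- as.character(fields$field_id[i])
    pred <- fields$ece_pred_dsm[i]

    set.seed(substream_seed(config$seed, paste0(fid, "|ece")))
    if (config$residual_mode == "dataset") {
      mu <- table$mean_residual[ds_row]
      sd_r <- table$sd_residual[ds_row]
    } else {
      row <- residual_row(pred, table)
      if (is.na(row)) row <- ds_row
      mu <- table$mean_residual[row]
      sd_r <- table$sd_residual[row]
    }
    ece <- pmax(pred - stats::rnorm(n_it, mu, sd_r), 0)

    b <- lf <- th <- NULL
    if (has_b[i]) {
      set.seed(substream_seed(config$seed, paste0(fid, "|b")))
      b <- rlnorm_matched(n_it, b_mean[i], b_sd[i],
                          finite_bounds(b_bnd$lo[i], b_bnd$hi[i]))
    }
    if (has_lf[i]) {
      set.seed(substream_seed(config$seed, paste0(fid, "|lf")))
      lf <- pmin(rlnorm_matched(n_it, lf_mean[i], lf_sd[i], NULL), 1)
    }
    if (has_theta[i]) {
      set.seed(substream_seed(config$seed, paste0(fid, "|theta")))
      th <- pmin(rlnorm_matched(n_it, th_mean[i], th_sd[i],
                                finite_bounds(th_bnd$lo[i], th_bnd$hi[i])), 1)
    }

    if (!has_b[i]) {
      # salinity tolerance alone
      yield <- if (quad) predict_yield_quadratic(ece, qs) else
        config$y_max * relative_yield_salt(ece, salt_params) / 100
    } else {
      if (quad) {
        tol <- pmin(predict_yield_quadratic(ece, qs),
                    predict_yield_quadratic(b, qb))
      } else {
        tol <- config$y_max *
          pmin(relative_yield_salt(ece, salt_params),
               relative_yield_boron(b, boron_params)) / 100
      }
      full_ok <- has_lf[i] && has_theta[i] && texture[i] != "coarse"
      if (full_ok) {
        in_range <- b >= rng$b[1] & b <= rng$b[2] &
          ece >= rng$ece[1] & ece <= rng$ece[2] &
          lf >= rng$lf[1] & lf <= rng$lf[2] &
          th >= rng$theta_g[1] & th <= rng$theta_g[2]
        yield <- ifelse(in_range,
                        yield_polynomial(b, ece, lf, th, coeffs), tol)
      } else {
        yield <- tol
      }
    }
    Q <- Q + fields$area_ha[i] * biofuel_mass_to_volume(
      oilseed_to_biofuel_mass(yield, conversion), conversion)
  }
  Q <- Q / 1e6

  structure(list(
    draws = tibble::tibble(iteration = seq_len(n_it), Q_ML = Q),
    summary = q_summary(Q),
    config = config
  ), class = "saltoil_simulation")
}

finite_bounds <- function(lo, hi) {
  if (!is.finite(lo) && !is.finite(hi)) NULL else c(lo, hi)
}

# distribution summary: skewness and kurtosis from standardized central
# moments; kurtosis is non-excess (normal = 3)
q_summary <- function(q) {
  m <- mean(q)
  cm <- function(k) mean((q - m)^k)
  v <- cm(2)
  tibble::tibble(
    mean = m,
    median = stats::median(q),
    sd = stats::sd(q),
    skewness = cm(3) / v^1.5,
    kurtosis = cm(4) / v^2,
    n = length(q)
  )
}

#' Scale a simulation for an intercropping scenario
#'
#' Planting the oilseed between orchard rows adds acreage roughly
#' proportional to production; the scenario scales every simulated regional
#' total by `(1 + uplift_fraction)` and recomputes the summary.
#'
#' @param result A `saltoil_simulation`.
#' @param uplift_fraction Fractional production uplift (>= 0; the plausible
#'   range for orchard intercropping is 0.15-0.30).
#' @return A new `saltoil_simulation`.
#' @export
apply_intercropping_scenario <- function(result, uplift_fraction) {
  stopifnot(inherits(result, "saltoil_simulation"))
  if (uplift_fraction < 0) stop("uplift_fraction must be non-negative",
                                call. = FALSE)
  q <- result$draws$Q_ML * (1 + uplift_fraction)
  structure(list(
    draws = tibble::tibble(iteration = result$draws$iteration, Q_ML = q),
    summary = q_summary(q),
    config = result$config
  ), class = "saltoil_simulation")
}

#' @export
print.saltoil_simulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Regional biofuel Monte Carlo: %d iterations\n", s$n))
  cat(sprintf("  Q mean %.1f ML/yr, median %.1f, sd %.1f, skew %.2f, kurt %.2f\n",
              s$mean, s$median, s$sd, s$skewness, s$kurtosis))
  invisible(x)
}

#' Per-iteration draws of a simulation
#' @param x A `saltoil_simulation`.
#' @param ... Unused.
#' @return A tibble with `iteration` and `Q_ML`.
#' @export
tidy.saltoil_simulation <- function(x, ...) x$draws

#' One-row summary of a simulation
#' @param x A `saltoil_simulation`.
#' @param ... Unused.
#' @return A one-row tibble of distribution statistics.
#' @export
glance.saltoil_simulation <- function(x, ...) x$summary
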