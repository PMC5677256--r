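#' Residual uncertainty table for predicted root-zone salinity
#'
#' The regional salinity predictions carry category-wise residual error
#' (residual = predicted - observed). The default table gives, for each
#' 1 dS/m category of predicted EC_e from 0 up to 16, for the open-ended
#' `>= 16` category, and for the entire data set, the mean residual, the
#' residual standard deviation and the data count behind them. Category
#' bins are half-open `[k, k+1)`; the positive means in the highest
#' categories correct a known over-prediction at high salinity.
#'
#' @param table Optional replacement data frame with columns `lower`,
#'   `mean_residual`, `sd_residual`, `count` plus one row with
#'   `lower = NA` for the whole-data-set PDF.
#' @return A tibble of class `residual_table`.
#' @export
residual_table <- function(table = NULL) {
  if (is.null(table)) {
    table <- tibble::tibble(
      lower = c(0:16, NA),
      mean_residual = c(-2.29, -0.38, -0.68, -0.32, -0.86, -0.97, -0.95,
                        -0.75, -0.86, -0.52, -0.50, 1.27, 2.18, 3.00, 3.64,
                        4.91, 6.57, 0.14),
      sd_residual = c(3.38, 2.13, 2.39, 2.21, 2.62, 2.45, 2.49, 2.69, 3.01,
                      2.67, 3.03, 2.38, 1.51, 1.69, 1.65, 2.07, 2.60, 3.11),
      count = c(131, 577, 623, 584, 351, 245, 298, 267, 215, 143, 82, 83,
                121, 193, 127, 77, 194, 4311)
    )
  }
  table <- tibble::as_tibble(table)
  stopifnot(all(c("lower", "mean_residual", "sd_residual", "count") %in%
                  names(table)),
            all(table$sd_residual >= 0),
            sum(is.na(table$lower)) == 1)
  lowers <- sort(table$lower[!is.na(table$lower)])
  stopifnot(!anyDuplicated(lowers))
  structure(table, class = c("residual_table", class(table)))
}

#' Lognormal input PDFs for boron, leaching fraction and water content
#'
#' Each of B, LF and theta_g is drawn from a lognormal distribution whose
#' natural-scale mean and SD match the configured targets (moment matching),
#' optionally truncated to `[min, max]` bounds (e.g. soil-survey ranges) by
#' rejection resampling. Defaults match the trial marginal statistics
#' (B 10.03/6.06 mg/L, LF 0.27/0.15, theta_g 0.19/0.05); these stand in for
#' the long-term regional dataset the study drew on, which is unpublished.
#'
#' @param b_mean,b_sd,lf_mean,lf_sd,theta_mean,theta_sd Natural-scale
#'   target mean and SD for each input; an SD of 0 gives a degenerate
#'   (constant) input.
#' @param b_bounds,lf_bounds,theta_bounds Optional length-2 truncation
#'   bounds.
#' @return An object of class `input_pdfs`.
#' @export
input_pdfs <- function(b_mean = 10.03, b_sd = 6.06,
                       lf_mean = 0.27, lf_sd = 0.15,
                       theta_mean = 0.19, theta_sd = 0.05,
                       b_bounds = NULL, lf_bounds = NULL,
                       theta_bounds = NULL) {
  chk <- function(m, s, bounds, name) {
    stopifnot(m > 0, s >= 0)
    if (!is.null(bounds)) {
      stopifnot(length(bounds) == 2)
      if (bounds[2] < bounds[1]) {
        stop("infeasible ", name, " bounds: max < min", call. = FALSE)
      }
    }
  }
  chk(b_mean, b_sd, b_bounds, "B")
  chk(lf_mean, lf_sd, lf_bounds, "LF")
  chk(theta_mean, theta_sd, theta_bounds, "theta_g")
  structure(list(
    b = list(mean = b_mean, sd = b_sd, bounds = b_bounds),
    lf = list(mean = lf_mean, sd = lf_sd, bounds = lf_bounds),
    theta_g = list(mean = theta_mean, sd = theta_sd, bounds = theta_bounds)
  ), class = "input_pdfs")
}

# lognormal (meanlog, sdlog) matching a natural-scale mean and SD
lnorm_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# moment-matched lognormal draws, rejection-resampled into bounds
rlnorm_matched <- function(n, mean, sd, bounds = NULL) {
  if (sd == 0) {
    x <- rep(mean, n)
  } else {
    p <- lnorm_pars(mean, sd)
    x <- stats::rlnorm(n, p$meanlog, p$sdlog)
  }
  if (!is.null(bounds)) {
    for (i in 1:1000) {
      bad <- x < bounds[1] | x > bounds[2]
      if (!any(bad)) break
      if (sd == 0) {
        x[bad] <- pmin(pmax(x[bad], bounds[1]), bounds[2])
        break
      }
      x[bad] <- stats::rlnorm(sum(bad), p$meanlog, p$sdlog)
    }
    x <- pmin(pmax(x, bounds[1]), bounds[2])
  }
  x
}

#' Leaching fraction from the EM coil-orientation ratio
#'
#' The ratio of the horizontal-coil to vertical-coil apparent conductivity
#' readings estimates the leaching fraction; the horizontal coil senses the
#' upper ~1 m and the vertical coil ~1.5 m. The ratio is clipped to the
#' physical range \[0, 1\].
#'
#' @param em_h,em_v Apparent conductivity in horizontal / vertical coil
#'   orientation, dS/m. `em_v` must be positive.
#' @return Leaching fraction estimate in \[0, 1\].
#' @export
lf_from_em_ratio <- function(em_h, em_v) {
  if (any(em_v <= 0)) stop("em_v must be positive", call. = FALSE)
  pmin(pmax(em_h / em_v, 0), 1)
}

#' Leaching fraction from the chloride concentration ratio
#'
#' The ratio of chloride concentration in irrigation water to that just
#' below the root zone (1.2-1.5 m) estimates the leaching fraction, clipped
#' to \[0, 1\].
#'
#' @param cl_irrigation Chloride in irrigation water, meq/L.
#' @param cl_below_rootzone Chloride at 1.2-1.5 m, meq/L (positive).
#' @return Leaching fraction estimate in \[0, 1\].
#' @export
lf_from_cl_ratio <- function(cl_irrigation, cl_below_rootzone) {
  if (any(cl_below_rootzone <= 0)) {
    stop("cl_below_rootzone must be positive", call. = FALSE)
  }
  pmin(pmax(cl_irrigation / cl_below_rootzone, 0), 1)
}

#' Reconcile two independent leaching-fraction estimates
#'
#' The EM-ratio and chloride-ratio estimates are accepted only when they
#' agree to within `tolerance` (relative to their mean); the accepted value
#' is their mean. Agreement is interpreted as relative difference.
#'
#' @param lf_em,lf_cl Estimates in \[0, 1\] (vectorised).
#' @param tolerance Maximum relative difference (default 0.05).
#' @return A tibble with `lf_em`, `lf_cl`, `accepted` (logical) and `lf`
#'   (the mean where accepted, `NA` otherwise).
#' @export
reconcile_lf <- function(lf_em, lf_cl, tolerance = 0.05) {
  stopifnot(all(lf_em >= 0 & lf_em <= 1), all(lf_cl >= 0 & lf_cl <= 1))
  m <- (lf_em + lf_cl) / 2
  rel <- ifelse(m == 0, 0, abs(lf_em - lf_cl) / m)
  ok <- rel <= tolerance
  tibble::tibble(lf_em = lf_em, lf_cl = lf_cl, accepted = ok,
                 lf = ifelse(ok, m, NA_real_))
}

#' Keep only salt-affected, croppable fields
#'
#' Fields with predicted mean root-zone EC_e below the salinity threshold
#' are not salt-affected and are disregarded; orchard and vineyard fields
#' are excluded because the regional salinity predictions are unreliable
#' there (and the land is not available for an annual oilseed crop).
#'
#' @param fields A data frame of field records with columns `ece_pred_dsm`
#'   and optionally `landcover`.
#' @param threshold Salinity threshold, dS/m (default 4; inclusive).
#' @return The retained rows, order preserved, as a tibble.
#' @export
filter_salt_affected <- function(fields, threshold = 4) {
  stopifnot(is.data.frame(fields), "ece_pred_dsm" %in% names(fields))
  fields <- tibble::as_tibble(fields)
  keep <- fields$ece_pred_dsm >= threshold
  if ("landcover" %in% names(fields)) {
    keep <- keep & !fields$landcover %in% c("orchard", "vineyard")
  }
  fields[keep, ]
}

# residual-table row index for a predicted ECe (half-open bins [k, k+1))
residual_row <- function(pred, table) {
  lowers <- table$lower[!is.na(table$lower)]
  idx <- findInterval(pred, sort(lowers))
  ifelse(idx == 0, NA_integer_, match(sort(lowers)[idx], table$lower))
}

#' Sample observed EC_e from a predicted value and its residual PDF
#'
#' The residual convention is `residual = predicted - observed`, so a
#' sampled plausible observed salinity is
#' `predicted - rnorm(mean_residual, sd_residual)` for the matching
#' salinity category (or the whole-data-set PDF), truncated below at 0.
#'
#' @param fields A data frame with column `ece_pred_dsm`.
#' @param table A [residual_table()].
#' @param mode `"dataset"` (whole-data-set PDF, default) or `"category"`.
#' @return `fields` as a tibble with an added `ece` column of sampled
#'   salinities.
#' @export
draw_ece <- function(fields, table = residual_table(),
                     mode = c("dataset", "category")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(fields), "ece_pred_dsm" %in% names(fields),
            inherits(table, "residual_table"))
  fields <- tibble::as_tibble(fields)
  pred <- fields$ece_pred_dsm
  ds_row <- which(is.na(table$lower))
  if (mode == "dataset") {
    mu <- rep(table$mean_residual[ds_row], length(pred))
    sd <- rep(table$sd_residual[ds_row], length(pred))
  } else {
    idx <- residual_row(pred, table)
    if (anyNA(idx)) {
      warning("predicted EC_e below the lowest category; using the ",
              "whole-data-set PDF", call. = FALSE)
      idx[is.na(idx)] <- ds_row
    }
    mu <- table$mean_residual[idx]
    sd <- table$sd_residual[idx]
  }
  fields$ece <- pmax(pred - stats::rnorm(length(pred), mu, sd), 0)
  fields
}

#' Draw boron, leaching fraction and water content for each field
#'
#' Independent moment-matched lognormal draws per field, rejection-resampled
#' into any truncation bounds; LF and theta_g are additionally clipped to
#' \[0, 1\]. Per-field PDF parameter columns (`b_mean`, `b_sd`, `lf_mean`,
#' `lf_sd`, `theta_mean`, `theta_sd`, and bound columns `b_min`, `b_max`,
#' `theta_min`, `theta_max`) override the defaults in `pdfs` where present
#' and non-missing.
#'
#' @param fields A data frame of field records.
#' @param pdfs An [input_pdfs()] object of default parameters.
#' @return `fields` as a tibble with added `b`, `lf`, `theta_g` columns.
#' @export
draw_inputs <- function(fields, pdfs = input_pdfs()) {
  stopifnot(is.data.frame(fields), inherits(pdfs, "input_pdfs"))
  fields <- tibble::as_tibble(fields)
  n <- nrow(fields)
  col_or <- function(col, default) {
    if (col %in% names(fields)) {
      ifelse(is.na(fields[[col]]), default, fields[[col]])
    } else {
      rep(default, n)
    }
  }
  draw_one <- function(pdf_key, prefix, bound_min_col, bound_max_col) {
    mean <- col_or(paste0(prefix, "_mean"), pdfs[[pdf_key]]$mean)
    sd <- col_or(paste0(prefix, "_sd"), pdfs[[pdf_key]]$sd)
    def_b <- pdfs[[pdf_key]]$bounds
    lo <- col_or(bound_min_col, if (is.null(def_b)) -Inf else def_b[1])
    hi <- col_or(bound_max_col, if (is.null(def_b)) Inf else def_b[2])
    if (any(hi < lo)) stop("infeasible bounds: max < min", call. = FALSE)
    x <- numeric(n)
    for (grp in split(seq_len(n), interaction(mean, sd, lo, hi, drop = TRUE))) {
      b <- c(lo[grp[1]], hi[grp[1]])
      if (!is.finite(b[1]) && !is.finite(b[2])) b <- NULL
      x[grp] <- rlnorm_matched(length(grp), mean[grp[1]], sd[grp[1]], b)
    }
    x
  }
  fields$b <- draw_one("b", "b", "b_min", "b_max")
  fields$lf <- pmin(draw_one("lf", "lf", "lf_min", "lf_max"), 1)
  fields$theta_g <- pmin(draw_one("theta_g", "theta", "theta_min", "theta_max"), 1)
  fields
}
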