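#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the salinity and boron tolerance curves
#'
#' Piecewise (relative yield, %) and quadratic (absolute yield, kg/ha)
#' tolerance curves over a stressor grid.
#'
#' @param salt_params A [salt_tolerance()] object.
#' @param boron_params A [boron_tolerance()] object.
#' @param quad_salt,quad_boron [quadratic_tolerance()] curves.
#' @param max_ece,max_b Upper plot limits.
#' @return A ggplot object, faceted by stressor and curve family.
#' @export
plot_tolerance_curves <- function(salt_params = salt_tolerance(),
                                  boron_params = boron_tolerance(),
                                  quad_salt = quadratic_salt(),
                                  quad_boron = quadratic_boron(),
                                  max_ece = 20, max_b = 15) {
  ece <- seq(0, max_ece, length.out = 400)
  b <- seq(0, max_b, length.out = 400)
  df <- dplyr::bind_rows(
    tibble::tibble(stressor = "ECe (dS/m)", family = "piecewise (%)",
                   x = ece, y = relative_yield_salt(ece, salt_params)),
    tibble::tibble(stressor = "B (mg/L)", family = "piecewise (%)",
                   x = b, y = relative_yield_boron(b, boron_params)),
    tibble::tibble(stressor = "ECe (dS/m)", family = "quadratic (kg/ha)",
                   x = ece, y = predict_yield_quadratic(ece, quad_salt)),
    tibble::tibble(stressor = "B (mg/L)", family = "quadratic (kg/ha)",
                   x = b, y = predict_yield_quadratic(b, quad_boron))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(family ~ stressor, scales = "free") +
    ggplot2::labs(x = "stressor level", y = "yield",
                  title = "Oilseed tolerance curves") +
    ggplot2::theme_minimal()
}

#' Plot the 1-SD sensitivity table
#'
#' @param sens A table from [sensitivity_analysis()].
#' @return A ggplot bar chart of percent yield change per shifted input.
#' @export
plot_sensitivity <- function(sens = sensitivity_analysis()) {
  df <- dplyr::filter(sens, !is.na(.data$pct_change))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$scenario, .data$pct_change),
    y = .data$pct_change)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% yield change vs baseline",
                  title = "Yield sensitivity to 1-SD input shifts") +
    ggplot2::theme_minimal()
}

#' Histogram of simulated production with fitted shifted-gamma density
#'
#' @param object A `saltoil_simulation`.
#' @param fit Optional [shifted_gamma()]; fitted by moments if omitted.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object; the vertical line marks the production target.
#' @export
autoplot.saltoil_simulation <- function(object, fit = NULL, bins = 40, ...) {
  q <- object$draws$Q_ML
  if (is.null(fit)) fit <- fit_shifted_gamma(q)
  grid <- seq(min(q), max(q), length.out = 400)
  dens <- tibble::tibble(
    x = grid,
    y = stats::dgamma(pmax(grid - fit$shift, 0), shape = fit$shape,
                      scale = fit$scale)
  )
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$Q_ML)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_vline(xintercept = object$config$target_ml,
                        linetype = "dashed") +
    ggplot2::labs(x = "regional biofuel production Q (ML/yr)",
                  y = "density",
                  title = "Monte Carlo production distribution") +
    ggplot2::theme_minimal()
}

#' Empirical and fitted cumulative distribution of production
#'
#' @param object A `saltoil_feasibility` report.
#' @param samples The Q draws behind the report.
#' @param ... Unused.
#' @return A ggplot object of the CDF with the target marked.
#' @export
autoplot.saltoil_feasibility <- function(object, samples, ...) {
  fit <- object$fit
  grid <- seq(min(samples), max(samples), length.out = 400)
  df <- tibble::tibble(
    x = grid,
    fitted = stats::pgamma(pmax(grid - fit$shift, 0), shape = fit$shape,
                           scale = fit$scale)
  )
  ggplot2::ggplot() +
    ggplot2::stat_ecdf(data = tibble::tibble(q = samples),
                       ggplot2::aes(x = .data$q), colour = "grey50") +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(x = .data$x, y = .data$fitted)) +
    ggplot2::geom_vline(xintercept = object$target_ml,
                        linetype = "dashed") +
    ggplot2::labs(x = "Q (ML/yr)", y = "P(Q <= q)",
                  title = "Production CDF: empirical vs shifted gamma") +
    ggplot2::theme_minimal()
}
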