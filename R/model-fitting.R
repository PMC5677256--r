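#' Fit the full polynomial yield regression from trial data
#'
#' Ordinary least squares fit of oilseed yield on
#' `{B, B^2, ECe, ECe^2, LF, theta_g}` with intercept, using only sites
#' with positive yield (zero-yield sites are excluded from model
#' development). An optional generalized-least-squares refit with an
#' exponential distance-decay correlation is available for spatially
#' autocorrelated trials.
#'
#' @param data A data frame with columns `yield_kg_ha`, `b`, `ece`, `lf`,
#'   `theta_g`, and (for `spatial = TRUE`) `x_m`, `y_m`.
#' @param spatial If `TRUE`, refit by GLS with `nlme::corExp` on the site
#'   coordinates.
#' @param range_m Correlation range (metres) for the spatial option.
#' @return An object of class `saltoil_fit`: the underlying model plus a
#'   coefficient table. Use [tidy()] / [glance()] to extract results.
#' @export
fit_yield_regression <- function(data, spatial = FALSE, range_m = 50) {
  stopifnot(is.data.frame(data))
  needed <- c("yield_kg_ha", "b", "ece", "lf", "theta_g")
  missing_col <- setdiff(needed, names(data))
  if (length(missing_col) > 0) {
    stop("missing column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  data <- dplyr::filter(tibble::as_tibble(data), .data$yield_kg_ha > 0)
  if (nrow(data) < 10) {
    stop("need at least 10 sites with positive yield", call. = FALSE)
  }
  form <- yield_kg_ha ~ b + I(b^2) + ece + I(ece^2) + lf + theta_g
  fit <- stats::lm(form, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("singular design: a regressor is collinear or constant",
         call. = FALSE)
  }
  if (spatial) {
    if (!all(c("x_m", "y_m") %in% names(data))) {
      stop("spatial fit needs x_m and y_m coordinates", call. = FALSE)
    }
    if (!requireNamespace("nlme", quietly = TRUE)) {
      stop("package 'nlme' is required for the spatial option", call. = FALSE)
    }
    fit <- nlme::gls(form, data = data,
                     correlation = nlme::corExp(value = range_m,
                                                form = ~ x_m + y_m))
  }
  new_saltoil_fit(fit, data, retained = c("b", "I(b^2)", "ece", "I(ece^2)",
                                          "lf", "theta_g"))
}

new_saltoil_fit <- function(fit, data, retained) {
  structure(list(fit = fit, data = data, retained = retained),
            class = "saltoil_fit")
}

#' @export
print.saltoil_fit <- function(x, ...) {
  cat("Oilseed yield regression fit\n")
  print(tidy(x))
  g <- glance(x)
  cat(sprintf("R-squared %.3f, adjusted %.3f, n = %d\n",
              g$r_squared, g$adj_r_squared, g$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a fitted yield regression
#'
#' @param x A `saltoil_fit` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `t_score`.
#' @export
# summary() on an exact (noiseless) fit warns about unreliable inference;
# exact fits are a designed use here, so muffle only that warning
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

tidy.saltoil_fit <- function(x, ...) {
  sm <- quiet_summary(x$fit)
  ct <- if (inherits(x$fit, "lm")) sm$coefficients else sm$tTable
  tibble::tibble(
    term = rownames(ct),
    estimate = ct[, 1],
    std_error = ct[, 2],
    t_score = ct[, 3]
  )
}

#' Fit summary of a yield regression
#'
#' @param x A `saltoil_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `r_squared`, `adj_r_squared`, `sigma`, `n`.
#' @export
glance.saltoil_fit <- function(x, ...) {
  resid <- stats::residuals(x$fit)
  fitted <- stats::fitted(x$fit)
  y <- resid + fitted
  n <- length(y)
  p <- length(stats::coef(x$fit)) - 1
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  tibble::tibble(
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    sigma = sqrt(rss / (n - p - 1)),
    n = n
  )
}

#' @export
residuals.saltoil_fit <- function(object, ...) stats::residuals(object$fit)

#' Backward t-score screening of candidate predictors
#'
#' Starting from an OLS fit of yield on all candidate predictors, the
#' predictor with the smallest absolute t-score is dropped while that score
#' is below `t_threshold`, refitting after each drop. Ties break by the
#' fixed candidate ordering (the earlier-listed term is dropped first).
#' Screening out clearly nonsignificant terms also damps multicollinearity
#' among the edaphic regressors.
#'
#' @param data Trial data frame with `yield_kg_ha` and every candidate term.
#' @param candidates Character vector of model terms (columns of `data` or
#'   expressions such as `"I(b^2)"`). Defaults to the full-model regressors.
#' @param t_threshold Screening threshold on |t| (default 1.8).
#' @return A list with `retained` (character vector) and `fit`
#'   (a `saltoil_fit`; intercept-only with a warning if nothing survives).
#' @export
backward_select <- function(data,
                            candidates = c("b", "I(b^2)", "ece", "I(ece^2)",
                                           "lf", "theta_g"),
                            t_threshold = 1.8) {
  stopifnot(is.data.frame(data), length(candidates) >= 1, t_threshold >= 0)
  data <- dplyr::filter(tibble::as_tibble(data), .data$yield_kg_ha > 0)
  kept <- candidates
  repeat {
    form <- stats::reformulate(if (length(kept) > 0) kept else "1",
                               response = "yield_kg_ha")
    fit <- stats::lm(form, data = data)
    if (length(kept) == 0) {
      warning("no predictor survived screening; returning intercept-only fit",
              call. = FALSE)
      return(list(retained = character(0),
                  fit = new_saltoil_fit(fit, data, character(0))))
    }
    ct <- quiet_summary(fit)$coefficients
    tt <- abs(ct[match(kept, rownames(ct)), 3])
    tt[is.na(tt)] <- 0  # aliased terms are clearly removable
    if (all(tt >= t_threshold)) {
      return(list(retained = kept, fit = new_saltoil_fit(fit, data, kept)))
    }
    kept <- kept[-which.min(tt)]  # which.min takes the first on ties
  }
}

#' Fit the two-piece linear salt tolerance model
#'
#' Grid-searches the salinity threshold `a` over the observed EC_e range;
#' for each candidate the plateau is fixed at 100% and the declining slope
#' `b` is fit by least squares on the points above `a`. The `(a, b)` pair
#' minimizing total squared error wins. Grid search keeps the breakpoint
#' estimate deterministic and robust on small trials.
#'
#' @param data A data frame with columns `ece` and `relative_yield` (%).
#' @param grid_step Breakpoint grid spacing, dS/m (default 0.05).
#' @return A list with `params` ([salt_tolerance()]), `sse`, and the
#'   searched `grid_step`.
#' @export
fit_two_piece_salt <- function(data, grid_step = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("ece", "relative_yield") %in% names(data)))
  ece <- data$ece
  ry <- data$relative_yield
  stopifnot(length(ece) >= 4)
  if (stats::sd(ry) == 0 || stats::cor(ece, ry) >= 0) {
    stop("no declining segment detected: data are all plateau or slope upward",
         call. = FALSE)
  }
  grid <- seq(min(ece), max(ece), by = grid_step)
  grid <- grid[grid < max(ece)]  # need at least one point above the break
  best <- NULL
  for (a in grid) {
    above <- ece > a
    if (sum(above) < 2) next
    dx <- ece[above] - a
    # least-squares slope with plateau pinned at 100
    b <- sum((100 - ry[above]) * dx) / sum(dx^2)
    if (b <= 0) next
    pred <- ifelse(above, 100 - b * (ece - a), 100)
    sse <- sum((ry - pred)^2)
    if (is.null(best) || sse < best$sse) best <- list(a = a, b = b, sse = sse)
  }
  if (is.null(best)) {
    stop("no declining segment detected: data are all plateau or slope upward",
         call. = FALSE)
  }
  list(params = salt_tolerance(best$a, best$b), sse = best$sse,
       grid_step = grid_step)
}

#' Fit the three-piece linear boron tolerance model
#'
#' 2-D grid search over the deficiency and toxicity thresholds; the plateau
#' is fixed at 100% and each outer segment's slope is fit by least squares.
#' Requires at least 2 points on each side outside the plateau.
#'
#' @param data A data frame with columns `b` and `relative_yield` (%).
#' @param grid_step Threshold grid spacing, mg/L (default 0.05).
#' @return A list with `params` ([boron_tolerance()]), `sse`, `grid_step`.
#' @export
fit_three_piece_boron <- function(data, grid_step = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("b", "relative_yield") %in% names(data)))
  b <- data$b
  ry <- data$relative_yield
  grid <- seq(min(b), max(b), by = grid_step)
  lo_ok <- vapply(grid, function(d) sum(b < d) >= 2, logical(1))
  hi_ok <- vapply(grid, function(t) sum(b > t) >= 2, logical(1))
  if (!any(lo_ok) || !any(hi_ok)) {
    stop("segment underdetermined: need at least 2 points below and above ",
         "the plateau", call. = FALSE)
  }
  best <- NULL
  for (d in grid[lo_ok]) {
    for (t in grid[hi_ok]) {
      if (d >= t) next
      below <- b < d
      above <- b > t
      dl <- d - b[below]
      dt <- b[above] - t
      s_def <- sum((100 - ry[below]) * dl) / sum(dl^2)
      s_tox <- sum((100 - ry[above]) * dt) / sum(dt^2)
      if (s_def <= 0 || s_tox <= 0) next
      pred <- rep(100, length(b))
      pred[below] <- 100 - s_def * dl
      pred[above] <- 100 - s_tox * dt
      sse <- sum((ry - pred)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(d = d, t = t, s_def = s_def, s_tox = s_tox, sse = sse)
      }
    }
  }
  if (is.null(best)) {
    stop("segment underdetermined: no feasible threshold pair with declining ",
         "outer segments", call. = FALSE)
  }
  list(params = boron_tolerance(best$d, best$t, best$s_tox, best$s_def),
       sse = best$sse, grid_step = grid_step)
}

#' Fit a quadratic tolerance curve by least squares
#'
#' @param data A data frame with columns `x` (stressor) and `yield_kg_ha`.
#' @return A list with `params` ([quadratic_tolerance()]), `r_squared`, and
#'   `vertex` (the stressor value of maximum yield).
#' @export
fit_quadratic_tolerance <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("x", "yield_kg_ha") %in% names(data)))
  if (length(unique(data$x)) < 3) {
    stop("underdetermined: need at least 3 distinct stressor values",
         call. = FALSE)
  }
  fit <- stats::lm(yield_kg_ha ~ x + I(x^2), data = data)
  cf <- stats::coef(fit)
  if (is.na(cf[3]) || cf[3] >= 0) {
    stop("fitted quadratic is not concave: no interior maximum", call. = FALSE)
  }
  params <- quadratic_tolerance(unname(cf[1]), unname(cf[2]), unname(cf[3]))
  list(params = params,
       r_squared = quiet_summary(fit)$r.squared,
       vertex = argmax_quadratic(params))
}
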