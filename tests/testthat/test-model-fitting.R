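test_that("OLS recovers generating coefficients exactly on noiseless data", {
  yc <- yield_coefficients()
  trial <- noiseless_trial()
  fit <- fit_yield_regression(trial)
  est <- tidy(fit)$estimate
  truth <- c(yc$beta0, yc$beta1, yc$beta2, yc$beta3, yc$beta4, yc$beta5,
             yc$beta6)
  expect_equal(unname(est), truth, tolerance = 1e-6)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-10)
})

test_that("coefficients land within 3 SE of truth under yield noise", {
  yc <- yield_coefficients()
  set.seed(7)
  trial <- noiseless_trial(n = 34, seed = 7)
  trial$yield_kg_ha <- pmax(trial$yield_kg_ha + rnorm(34, 0, 100), 0.1)
  fit <- fit_yield_regression(trial)
  tt <- tidy(fit)
  truth <- c(yc$beta0, yc$beta1, yc$beta2, yc$beta3, yc$beta4, yc$beta5,
             yc$beta6)
  expect_true(all(abs(tt$estimate - truth) <= 3 * tt$std_error))
})

test_that("degenerate designs raise a singular-design error", {
  trial <- noiseless_trial()
  trial$theta_g <- 0.2  # constant regressor
  expect_error(fit_yield_regression(trial), "singular")
  expect_error(fit_yield_regression(trial[1:5, ]), "at least 10")
})

test_that("zero-yield sites are excluded from model development", {
  trial <- noiseless_trial(n = 40)
  trial$yield_kg_ha[1:6] <- 0
  fit <- fit_yield_regression(trial)
  expect_equal(glance(fit)$n, 34)
})

test_that("adjusted R-squared never exceeds R-squared", {
  set.seed(11)
  trial <- noiseless_trial(n = 34, seed = 11)
  trial$yield_kg_ha <- pmax(trial$yield_kg_ha + rnorm(34, 0, 200), 0.1)
  g <- glance(fit_yield_regression(trial))
  expect_lte(g$adj_r_squared, g$r_squared)
  expect_gte(g$r_squared, 0)
  expect_lte(g$r_squared, 1)
})

test_that("backward screening drops a known-null covariate and keeps signal", {
  set.seed(3)
  n <- 200
  trial <- noiseless_trial(n = n, seed = 3)
  trial$ph_e <- rnorm(n, 7.7, 0.3)  # no effect on yield
  trial$yield_kg_ha <- pmax(trial$yield_kg_ha + rnorm(n, 0, 20), 0.1)
  sel <- backward_select(trial, candidates = c("b", "I(b^2)", "ece",
                                               "I(ece^2)", "lf", "theta_g",
                                               "ph_e"))
  expect_false("ph_e" %in% sel$retained)
  expect_true(all(c("b", "I(b^2)", "ece", "I(ece^2)", "lf", "theta_g") %in%
                    sel$retained))
})

test_that("a zero threshold retains every candidate", {
  trial <- noiseless_trial(n = 50, seed = 5)
  trial$ph_e <- rnorm(50, 7.7, 0.3)
  cand <- c("b", "ece", "lf", "theta_g", "ph_e")
  sel <- backward_select(trial, candidates = cand, t_threshold = 0)
  expect_setequal(sel$retained, cand)
})

test_that("pure-noise predictors screen down to the intercept", {
  set.seed(1)
  n <- 100
  trial <- tibble::tibble(
    yield_kg_ha = rlnorm(n, 6, 0.2),
    z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n)
  )
  expect_warning(
    sel <- backward_select(trial, candidates = c("z1", "z2", "z3"),
                           t_threshold = 1.8),
    "intercept-only"
  )
  expect_length(sel$retained, 0)
})

test_that("screening never drops a predictor at or above the threshold", {
  set.seed(21)
  for (s in 1:5) {
    n <- 60
    trial <- noiseless_trial(n = n, seed = 100 + s)
    trial$yield_kg_ha <- pmax(trial$yield_kg_ha + rnorm(n, 0, 150), 0.1)
    trial$ph_e <- rnorm(n, 7.7, 0.3)
    cand <- c("b", "I(b^2)", "ece", "I(ece^2)", "lf", "theta_g", "ph_e")
    sel <- backward_select(trial, candidates = cand)
    # every retained predictor has |t| >= threshold in the final fit
    tt <- tidy(sel$fit)
    final_t <- abs(tt$t_score[match(sel$retained, tt$term)])
    expect_true(all(final_t >= 1.8))
  }
})

test_that("two-piece salt fit recovers parameters from noiseless data", {
  fit <- fit_two_piece_salt(two_piece_data(), grid_step = 0.05)
  expect_equal(fit$params$threshold_a, 8.3, tolerance = 0.051 / 8.3)
  expect_equal(fit$params$slope_b, 17, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
})

test_that("two-piece salt fit is near truth under noise and grid-optimal", {
  set.seed(13)
  ece <- runif(50, 2, 14)
  truth <- salt_tolerance(8.3, 17)
  ry <- relative_yield_salt(ece, truth) + rnorm(50, 0, 5)
  data <- tibble::tibble(ece = ece, relative_yield = ry)
  fit <- fit_two_piece_salt(data)
  expect_equal(fit$params$threshold_a, 8.3, tolerance = 0.5 / 8.3)
  expect_equal(fit$params$slope_b, 17, tolerance = 2 / 17)
  # optimality over the searched grid: no worse than the generating params
  pred_truth <- relative_yield_salt(ece, truth)
  pred_truth <- ifelse(ece > truth$threshold_a,
                       100 - truth$slope_b * (ece - truth$threshold_a),
                       100)
  expect_lte(fit$sse, sum((ry - pred_truth)^2) + 1e-9)
})

test_that("all-plateau salt data raise a no-decline error", {
  flat <- tibble::tibble(ece = c(2, 3, 4, 5), relative_yield = 100)
  expect_error(fit_two_piece_salt(flat), "declin")
  rising <- tibble::tibble(ece = c(2, 4, 6, 8, 10),
                           relative_yield = c(80, 85, 90, 95, 100))
  expect_error(fit_two_piece_salt(rising), "declin")
})

test_that("three-piece boron fit recovers thresholds and slopes", {
  truth <- boron_tolerance(4.2, 8, 28, 100 / 4.2)
  fit <- fit_three_piece_boron(three_piece_data(truth), grid_step = 0.05)
  expect_equal(fit$params$deficiency_threshold, 4.2, tolerance = 0.051 / 4.2)
  expect_equal(fit$params$toxicity_threshold, 8, tolerance = 0.051 / 8)
  expect_equal(fit$params$toxicity_slope, 28, tolerance = 0.2 / 28)
  expect_equal(fit$params$deficiency_slope, 100 / 4.2, tolerance = 0.2 / 23)
})

test_that("three-piece boron fit is near truth under noise", {
  set.seed(17)
  truth <- boron_tolerance(4.2, 8, 28, 100 / 4.2)
  b <- runif(60, 0.5, 11)
  ry <- relative_yield_boron(b, truth) + rnorm(60, 0, 5)
  fit <- fit_three_piece_boron(tibble::tibble(b = b, relative_yield = ry))
  expect_equal(fit$params$deficiency_threshold, 4.2, tolerance = 0.5 / 4.2)
  expect_equal(fit$params$toxicity_threshold, 8, tolerance = 0.5 / 8)
})

test_that("plateau-only boron data raise a segment-underdetermined error", {
  inside <- tibble::tibble(b = seq(4.5, 7.5, by = 0.5), relative_yield = 100)
  expect_error(fit_three_piece_boron(inside), "underdetermined")
})

test_that("quadratic tolerance fit interpolates exactly and finds the vertex", {
  qs <- quadratic_salt()
  x <- c(2, 6, 10)
  exact <- tibble::tibble(x = x, yield_kg_ha = qs$c0 + qs$c1 * x + qs$c2 * x^2)
  fit <- fit_quadratic_tolerance(exact)
  expect_equal(c(fit$params$c0, fit$params$c1, fit$params$c2),
               c(74.0, 254.6, -18.8), tolerance = 1e-6)

  qb <- quadratic_boron()
  x <- seq(2, 11, length.out = 10)
  dat <- tibble::tibble(x = x, yield_kg_ha = qb$c0 + qb$c1 * x + qb$c2 * x^2)
  fitb <- fit_quadratic_tolerance(dat)
  expect_equal(fitb$vertex, 6.5472, tolerance = 1e-4)
  expect_equal(fitb$r_squared, 1, tolerance = 1e-10)

  expect_error(fit_quadratic_tolerance(exact[1:2, ]), "underdetermined")
})

test_that("regression error shrinks as the trial grows", {
  yc <- yield_coefficients()
  truth <- c(yc$beta0, yc$beta1, yc$beta2, yc$beta3, yc$beta4, yc$beta5,
             yc$beta6)
  rmse_at_n <- function(n, seeds) {
    errs <- vapply(seeds, function(s) {
      set.seed(s)
      trial <- noiseless_trial(n = n, seed = s)
      trial$yield_kg_ha <- pmax(trial$yield_kg_ha + rnorm(n, 0, 150), 0.1)
      est <- tidy(fit_yield_regression(trial))$estimate
      sqrt(mean(((est - truth) / truth)^2))
    }, numeric(1))
    mean(errs)
  }
  seeds <- 1:20
  expect_lt(rmse_at_n(340, seeds), rmse_at_n(34, seeds))
})
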