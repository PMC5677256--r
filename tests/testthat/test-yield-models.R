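test_that("full polynomial model reproduces the published sensitivity yields", {
  yc <- yield_coefficients()
  expect_equal(predict_yield_full(baseline_profile, yc)$yield_kg_ha,
               1017.3, tolerance = 0.1 / 1017.3)
  # intercept only
  origin <- tibble::tibble(b = 0, ece = 0, lf = 0, theta_g = 0)
  expect_equal(predict_yield_full(origin, yc)$yield_kg_ha, 30.1)
  # boron shifted one unrounded SD above baseline
  shifted <- dplyr::mutate(baseline_profile, b = 4.0 + 6.06)
  expect_equal(predict_yield_full(shifted, yc)$yield_kg_ha,
               345.2, tolerance = 0.1 / 345.2)
})

test_that("negative polynomial values are truncated at zero", {
  yc <- yield_coefficients()
  hostile <- tibble::tibble(b = 20, ece = 25, lf = 0.1, theta_g = 0.15)
  # raw polynomial is negative here (verified by direct evaluation)
  raw <- 30.1 + 146.4 * 20 - 18.3 * 400 + 83 * 25 - 6.1 * 625 +
    1301 * 0.1 + 319.8 * 0.15
  expect_lt(raw, 0)
  expect_equal(predict_yield_full(hostile, yc)$yield_kg_ha, 0)
})

test_that("missing regressors raise an error naming the input", {
  expect_error(predict_yield_full(tibble::tibble(b = 4, ece = 6.8, lf = 0.27)),
               "theta_g")
  with_na <- dplyr::mutate(baseline_profile, ece = NA_real_)
  expect_error(predict_yield_full(with_na), "ece")
})

test_that("two-piece salt tolerance follows threshold-slope form, floored", {
  st <- salt_tolerance()
  expect_equal(relative_yield_salt(5, st), 100)
  expect_equal(relative_yield_salt(9.3, st), 83)
  expect_equal(relative_yield_salt(20, st), 0)
  grid <- seq(0, 40, by = 0.1)
  ry <- relative_yield_salt(grid, st)
  expect_true(all(ry >= 0 & ry <= 100))
})

test_that("three-piece boron tolerance has plateau, two declines, and floor", {
  bt <- boron_tolerance()
  expect_equal(relative_yield_boron(6, bt), 100)
  expect_equal(relative_yield_boron(9, bt), 72)
  # zero yield at the printed toxic limit (within slope rounding)
  expect_lt(relative_yield_boron(11.6, bt), 1)
  expect_equal(relative_yield_boron(12, bt), 0)
  grid <- seq(0, 30, by = 0.05)
  ry <- relative_yield_boron(grid, bt)
  expect_true(all(ry >= 0 & ry <= 100))
  # deficiency side declines towards zero at B = 0 under the default slope
  expect_equal(relative_yield_boron(0, bt), 0, tolerance = 1e-10)
})

test_that("quadratic tolerance curves evaluate and floor correctly", {
  qs <- quadratic_salt()
  qb <- quadratic_boron()
  expect_equal(predict_yield_quadratic(0, qs), 74.0)
  expect_equal(predict_yield_quadratic(argmax_quadratic(qs), qs),
               936.0, tolerance = 0.5 / 936)
  expect_equal(predict_yield_quadratic(0, qb), 0)  # raw intercept is -418
  expect_equal(predict_yield_quadratic(argmax_quadratic(qb), qb),
               1399.5, tolerance = 0.5 / 1399.5)
})

test_that("argmax matches the printed points of maximum yield", {
  expect_equal(round(argmax_quadratic(c(83.0, -6.1)), 1), 6.8)
  expect_equal(argmax_quadratic(c(146.4, -18.3)), 4.0)
  expect_equal(round(argmax_quadratic(quadratic_salt()), 1), 6.8)
  expect_equal(round(argmax_quadratic(quadratic_boron()), 1), 6.5)
  expect_error(argmax_quadratic(c(1, 2)), "maximum")
})

test_that("argmax agrees with numerical maximization of the full model", {
  yc <- yield_coefficients()
  f <- function(x) {
    p <- baseline_profile
    p$ece <- x
    predict_yield_full(p, yc)$yield_kg_ha
  }
  num <- stats::optimize(f, c(0, 25), maximum = TRUE)$maximum
  expect_equal(argmax_quadratic(c(yc$beta3, yc$beta4)), num,
               tolerance = 1e-6)
})

test_that("full model is concave in B and in ECe around the argmax", {
  yc <- yield_coefficients()
  for (delta in c(0.01, 0.5, 2)) {
    amax_e <- argmax_quadratic(c(yc$beta3, yc$beta4))
    y <- function(x) {
      p <- baseline_profile
      p$ece <- x
      predict_yield_full(p, yc)$yield_kg_ha
    }
    expect_gt(y(amax_e), y(amax_e + delta))
    expect_gt(y(amax_e), y(amax_e - delta))
    amax_b <- argmax_quadratic(c(yc$beta1, yc$beta2))
    yb <- function(x) {
      p <- baseline_profile
      p$b <- x
      predict_yield_full(p, yc)$yield_kg_ha
    }
    expect_gt(yb(amax_b), yb(amax_b + delta))
    expect_gt(yb(amax_b), yb(amax_b - delta))
  }
})

test_that("zero-yield thresholds match analytic values and a grid scan", {
  expect_equal(zero_yield_threshold(salt_tolerance()), 8.3 + 100 / 17)
  expect_equal(round(zero_yield_threshold(boron_tolerance()), 2), 11.57)
  expect_equal(zero_yield_threshold(salt_tolerance(8.3, 100)), 9.3)
  # oracle: smallest ece on a fine grid where relative yield hits 0
  grid <- seq(0, 30, by = 1e-4)
  scanned <- grid[which(relative_yield_salt(grid, salt_tolerance()) == 0)[1]]
  expect_equal(zero_yield_threshold(salt_tolerance()), scanned,
               tolerance = 2e-4)
})

test_that("model selection maps every availability pattern to one choice", {
  yc <- yield_coefficients()
  vals <- list(b = 5, ece = 8, lf = 0.3, theta_g = 0.2)
  combos <- expand.grid(hb = c(TRUE, FALSE), he = c(TRUE, FALSE),
                        hl = c(TRUE, FALSE), ht = c(TRUE, FALSE))
  df <- tibble::tibble(
    b = ifelse(combos$hb, vals$b, NA_real_),
    ece = ifelse(combos$he, vals$ece, NA_real_),
    lf = ifelse(combos$hl, vals$lf, NA_real_),
    theta_g = ifelse(combos$ht, vals$theta_g, NA_real_)
  )
  out <- select_model(df, yc)
  expect_false(anyNA(out$model_choice))
  expect_true(all(out$model_choice %in%
                    c("FULL_MODEL", "TOLERANCE_MOST_LIMITING",
                      "SALT_TOLERANCE_ONLY", "OPTIMAL")))
  # spot checks on the hierarchy
  pick <- function(row) as.character(out$model_choice[row])
  expect_equal(pick(which(combos$hb & combos$he & combos$hl & combos$ht)),
               "FULL_MODEL")
  expect_equal(pick(which(!combos$hb & combos$he & !combos$hl & !combos$ht)),
               "SALT_TOLERANCE_ONLY")
  expect_equal(pick(which(!combos$hb & !combos$he & !combos$hl & !combos$ht)),
               "OPTIMAL")
})

test_that("out-of-range or coarse-texture fields drop to tolerance models", {
  yc <- yield_coefficients()
  df <- tibble::tibble(
    b = c(5, 5, 5), ece = c(35, 8, 8), lf = 0.3, theta_g = 0.2,
    texture = c("fine", "coarse", "fine")
  )
  out <- select_model(df, yc)
  expect_equal(as.character(out$model_choice),
               c("TOLERANCE_MOST_LIMITING", "TOLERANCE_MOST_LIMITING",
                 "FULL_MODEL"))
})

test_that("field yield prediction follows the chosen model", {
  # unstressed plateau
  opt <- tibble::tibble(b = NA_real_, ece = NA_real_, lf = NA_real_,
                        theta_g = NA_real_)
  expect_equal(predict_field_yield(opt, y_max = 936)$yield_kg_ha, 936)
  # salt tolerance alone scales y_max by relative yield
  salt_only <- tibble::tibble(b = NA_real_, ece = 9.3, lf = NA_real_,
                              theta_g = NA_real_)
  expect_equal(predict_field_yield(salt_only, y_max = 1000)$yield_kg_ha, 830)
  # most-limiting rule takes the minimum relative yield
  tol <- tibble::tibble(b = 9, ece = 5, lf = NA_real_, theta_g = NA_real_)
  expect_equal(predict_field_yield(tol, y_max = 1000)$yield_kg_ha, 720)
})

test_that("quadratic curve family uses absolute most-limiting yields", {
  tol <- tibble::tibble(b = 9, ece = 5, lf = NA_real_, theta_g = NA_real_)
  got <- predict_field_yield(tol, curve_family = "quadratic")$yield_kg_ha
  expected <- min(predict_yield_quadratic(5, quadratic_salt()),
                  predict_yield_quadratic(9, quadratic_boron()))
  expect_equal(got, expected)
})

test_that("sensitivity table reproduces published rows and is self-consistent", {
  sens <- sensitivity_analysis()
  expect_equal(sens$yield_kg_ha[sens$scenario == "Baseline"], 1017.3,
               tolerance = 0.1 / 1017.3)
  expect_equal(sens$biofuel_L_ha[sens$scenario == "Baseline"], 178.3,
               tolerance = 0.1 / 178.3)
  expect_equal(sens$yield_kg_ha[sens$scenario == "ECe + 1 SD"], 776.2,
               tolerance = 0.1 / 776.2)
  expect_equal(sens$pct_change[sens$scenario == "ECe + 1 SD"], -23.7,
               tolerance = 0.1 / 23.7)
  expect_equal(sens$pct_change[sens$scenario == "LF + 1 SD"], 19.2,
               tolerance = 0.1 / 19.2)
  expect_equal(sens$pct_change[sens$scenario == "theta_g + 1 SD"], 1.6,
               tolerance = 0.1 / 1.6)
  # percent changes recompute exactly from the yield column
  base <- sens$yield_kg_ha[1]
  expect_equal(sens$pct_change[-1],
               100 * (sens$yield_kg_ha[-1] - base) / base)
})
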