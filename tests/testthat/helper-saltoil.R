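# fixture builders shared across test files; everything is generated in code

# noiseless trial data sampled exactly from the full polynomial model
noiseless_trial <- function(n = 34, seed = 42, coeffs = yield_coefficients()) {
  set.seed(seed)
  tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n)),
    # ranges chosen so the generating polynomial stays positive everywhere
    b = runif(n, 2.5, 7.5),
    ece = runif(n, 2, 13),
    lf = runif(n, 0.1, 0.6),
    theta_g = runif(n, 0.12, 0.25)
  ) |>
    predict_yield_full(coeffs)
}

# exact two-piece salt tolerance observations (no noise)
two_piece_data <- function(a = 8.3, b = 17, ece = seq(2, 13.5, by = 0.5)) {
  tibble::tibble(
    ece = ece,
    relative_yield = relative_yield_salt(ece, salt_tolerance(a, b))
  )
}

# exact three-piece boron tolerance observations (no noise)
three_piece_data <- function(params = boron_tolerance(),
                             b = seq(0.5, 11, by = 0.25)) {
  tibble::tibble(b = b, relative_yield = relative_yield_boron(b, params))
}

baseline_profile <- tibble::tibble(b = 4.0, ece = 6.8, lf = 0.27,
                                   theta_g = 0.19)
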