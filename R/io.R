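#' Default configuration of model constants
#'
#' One versioned list holding every model constant the pipeline uses
#' (regression coefficients and ranges, tolerance parameters, quadratic
#' curves, conversion factors, input-PDF parameters, simulation defaults
#' and the production target), so runs pin to configuration rather than to
#' code literals.
#'
#' @return A named list.
#' @export
default_config <- function() {
  yc <- yield_coefficients()
  st <- salt_tolerance()
  bt <- boron_tolerance()
  qs <- quadratic_salt()
  qb <- quadratic_boron()
  cv <- conversion_params()
  pd <- input_pdfs()
  list(
    version = as.character(utils::packageVersion("saltoil")),
    yield_coefficients = yc[c("beta0", "beta1", "beta2", "beta3", "beta4",
                              "beta5", "beta6")],
    applicability_ranges = yc$ranges,
    salt_tolerance = unclass(st),
    boron_tolerance = unclass(bt),
    quadratic_salt = qs[c("c0", "c1", "c2")],
    quadratic_boron = qb[c("c0", "c1", "c2")],
    conversion = unclass(cv),
    input_pdfs = list(
      b = pd$b[c("mean", "sd")],
      lf = pd$lf[c("mean", "sd")],
      theta_g = pd$theta_g[c("mean", "sd")]
    ),
    simulation = list(n_iterations = 10000, target_ml = 115,
                      curve_family = "piecewise",
                      residual_mode = "dataset", y_max = 936),
    sensitivity = list(
      baseline = list(b = 4.0, ece = 6.8, lf = 0.27, theta_g = 0.19),
      sds = list(b = 6.06, ece = 6.29, lf = 0.15, theta_g = 0.05)
    )
  )
}

#' Read or write a configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) by file extension.
#'
#' @param path File path.
#' @param config A configuration list (for writing).
#' @return `read_config()` returns the list; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yml = ,
                yaml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format: .", ext, call. = FALSE))
  if (!is.list(cfg)) stop("malformed config file: ", path, call. = FALSE)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yml = ,
         yaml = yaml::write_yaml(config, path),
         json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}

check_columns <- function(df, required, known, path) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("schema error in ", path, ": missing required column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), known)
  if (length(extra) > 0) {
    warning("unknown column(s) in ", path, " preserved as-is: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

trial_file_cols <- c(site_id = "site_id", x_m = "x_m", y_m = "y_m",
                     yield_kg_ha = "yield_kg_ha", ece = "ece_dsm",
                     b = "b_mgL", lf = "lf", theta_g = "theta_g",
                     ph_e = "ph_e", sp = "sp", sar = "sar")

#' Read or write field-trial data as CSV
#'
#' One row per site with columns `site_id, x_m, y_m, yield_kg_ha, ece_dsm,
#' b_mgL, lf, theta_g, ph_e, sp, sar`; on read, the unit-suffixed columns
#' map to the package's `ece` / `b` names. Unknown extra columns are kept
#' with a warning. Validation is fail-fast: negative yields or salinities
#' abort before any computation.
#'
#' @param path CSV file path.
#' @param trial A trial tibble (for writing), e.g. from [generate_trial()].
#' @return `read_trial()` returns a tibble; `write_trial()` returns `path`
#'   invisibly.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, required = c("site_id", "yield_kg_ha", "ece_dsm",
                                 "b_mgL", "lf", "theta_g"),
                known = c(unname(trial_file_cols), "zero_yield"), path)
  names(df)[names(df) == "ece_dsm"] <- "ece"
  names(df)[names(df) == "b_mgL"] <- "b"
  if (any(df$yield_kg_ha < 0, na.rm = TRUE)) {
    stop("validation error in ", path, ": negative yield_kg_ha",
         call. = FALSE)
  }
  if (any(df$ece < 0, na.rm = TRUE)) {
    stop("validation error in ", path, ": negative ece_dsm", call. = FALSE)
  }
  df
}

#' @rdname read_trial
#' @export
write_trial <- function(trial, path) {
  out <- trial
  names(out)[names(out) == "ece"] <- "ece_dsm"
  names(out)[names(out) == "b"] <- "b_mgL"
  readr::write_csv(out, path)
  invisible(path)
}

field_known_cols <- c("field_id", "area_ha", "ece_pred_dsm", "texture",
                      "landcover", "b_mean", "b_sd", "lf_mean", "lf_sd",
                      "theta_mean", "theta_sd", "b_min", "b_max",
                      "theta_min", "theta_max", "has_b", "has_lf",
                      "has_theta")

#' Read or write regional field records as CSV
#'
#' Columns: `field_id, area_ha, ece_pred_dsm` (required) plus optional
#' `texture, landcover`, per-field PDF parameters (`b_mean, b_sd, lf_mean,
#' lf_sd, theta_mean, theta_sd`), bounds (`b_min, b_max, theta_min,
#' theta_max`) and availability flags (`has_b, has_lf, has_theta`).
#' Unknown extra columns are kept with a warning; non-positive areas or
#' negative salinities abort before any computation.
#'
#' @param path CSV file path.
#' @param fields A field-record tibble (for writing).
#' @return `read_field_table()` returns a tibble; `write_field_table()`
#'   returns `path` invisibly.
#' @export
read_field_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, required = c("field_id", "area_ha", "ece_pred_dsm"),
                known = field_known_cols, path)
  if (any(df$area_ha <= 0, na.rm = TRUE)) {
    stop("validation error in ", path, ": non-positive area_ha",
         call. = FALSE)
  }
  if (any(df$ece_pred_dsm < 0, na.rm = TRUE)) {
    stop("validation error in ", path, ": negative ece_pred_dsm",
         call. = FALSE)
  }
  df
}

#' @rdname read_field_table
#' @export
write_field_table <- function(fields, path) {
  readr::write_csv(fields, path)
  invisible(path)
}

#' Read or write the salinity residual table as CSV
#'
#' Columns `lower, mean_residual, sd_residual, count`, one row per
#' predicted-salinity category plus one whole-data-set row with empty
#' `lower`.
#'
#' @param path CSV file path.
#' @param table A [residual_table()] (for writing).
#' @return `read_residual_table()` returns a [residual_table()];
#'   `write_residual_table()` returns `path` invisibly.
#' @export
read_residual_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  residual_table(df)
}

#' @rdname read_residual_table
#' @export
write_residual_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(unclass(table)), path)
  invisible(path)
}
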