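#' Default run configuration
#'
#' A nested, YAML-serialisable list driving the whole pipeline: the synthetic
#' generator block, market prices, sub-level sweep grids, the target state
#' leaching reduction, welfare scaling constants, forest size and root seed.
#'
#' @param preset `"test"` (24 + 120 fields, 10 years) or `"full"`
#'   (240 + 4,030 fields, 30 years).
#' @param seed root seed.
#' @return a named list of class `nfp_run_config`.
#' @export
default_run_config <- function(preset = "test", seed = 1L) {
  structure(list(
    synthetic = list(preset = preset, seed = seed),
    prices = list(p_maize = 0.158, p_n = 0.79),
    sweeps = list(
      price_ratio = default_sublevels("price_ratio"),
      leaching_fee = default_sublevels("leaching_fee"),
      balance_fee = default_sublevels("balance_fee"),
      voluntary = default_sublevels("voluntary")
    ),
    target_reduction = 20,
    welfare = list(externality_cost_per_kg = 16.1, state_area = 4.4e6),
    num_trees = 300L,
    seed = as.integer(seed)
  ), class = "nfp_run_config")
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys raise a configuration error; missing keys fall back to
#' [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: an `nfp_run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "nfp_config_error")
  }
  user <- yaml::read_yaml(path)
  def <- default_run_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown) > 0) {
    abort(paste("unknown config key(s):", toString(unknown)),
          class = "nfp_config_error")
  }
  cfg <- utils::modifyList(unclass(def), user)
  structure(cfg, class = "nfp_run_config")
}

#' @rdname read_run_config
#' @param config an `nfp_run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# run-config synthetic block -> validated generator config
config_to_synth <- function(config) {
  do.call(synth_config, config$synthetic)
}

config_prices <- function(config) {
  prices(p_maize = config$prices$p_maize, p_n = config$prices$p_n)
}

#' Write a generated dataset as CSV tables
#'
#' `sites.csv` holds one row per field; `curves.csv` the long response-curve
#' table (field x year x N rate) joined with the v5 covariate columns;
#' `data_dictionary.csv` documents every column and unit.
#'
#' @param dataset an [generate_dataset()] object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$sites, file.path(dir, "sites.csv"))
  curves <- dplyr::left_join(
    dataset$curves,
    dplyr::select(dataset$covariates, -"region", -"role"),
    by = c("field_id", "year"))
  readr::write_csv(curves, file.path(dir, "curves.csv"))
  readr::write_csv(nfp_data_dictionary(), file.path(dir, "data_dictionary.csv"))
  invisible(dir)
}

#' Read a user-supplied response-curve table
#'
#' Accepts any CSV shaped like `curves.csv` (long format with at least
#' `field_id`, `year`, `region`, `role`, `n_rate`, `yield`, `leach2` and the
#' [v5_covariates()]), validates it, and wraps it as an `nfp_dataset` usable
#' by the pipeline.
#'
#' @param path CSV path.
#' @param n_grid expected N-rate grid.
#' @return an `nfp_dataset` (without latent `params`).
#' @export
read_curves_csv <- function(path, n_grid = seq(0, 320, by = 10)) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("field_id", "year", "region", "role", "n_rate", "yield", "leach2",
            v5_covariates())
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(paste("curves CSV is missing columns:", toString(miss)),
          class = "nfp_data_error")
  }
  grid_ok <- d %>%
    dplyr::group_by(.data$field_id, .data$year) %>%
    dplyr::summarise(ok = all(sort(.data$n_rate) == n_grid), .groups = "drop")
  if (!all(grid_ok$ok)) {
    abort("every field-year must tabulate the full N grid",
          class = "nfp_data_error")
  }
  covariates <- dplyr::distinct(
    d, dplyr::across(dplyr::all_of(c("field_id", "year", "region", "role",
                                     v5_covariates()))))
  curves <- dplyr::select(d, "field_id", "year", "region", "role", "n_rate",
                          "yield", "leach2")
  sites <- dplyr::distinct(d, .data$field_id, .data$region, .data$role)
  weather <- dplyr::distinct(d, year = .data$year)
  cfg <- synth_config(n_trial = max(2, sum(sites$role == "trial")),
                      n_eval = max(2, sum(sites$role == "evaluation")),
                      n_years = max(2, nrow(weather)), n_grid = n_grid)
  structure(list(sites = sites, weather = weather, curves = curves,
                 covariates = covariates, params = NULL, config = cfg),
            class = "nfp_dataset")
}

nfp_data_dictionary <- function() {
  tibble::tribble(
    ~column, ~unit, ~description,
    "field_id", "-", "field identifier",
    "year", "-", "weather year (shared by all fields)",
    "region", "-", "south / central / north",
    "role", "-", "trial (response curves feed the recommender) or evaluation",
    "rotation_phase", "-", "0/1: maize in even/odd year indices",
    "n_rate", "kg N/ha", "fertilizer N rate on the 0-320 grid",
    "yield", "kg grain/ha", "maize grain yield at n_rate",
    "leach2", "kg N/ha", "N leached over maize + following soybean year",
    "som", "%", "soil organic matter",
    "sand", "%", "sand content",
    "clay", "%", "clay content",
    "whc", "mm", "water holding capacity",
    "long_term_yield", "kg/ha", "long-term attainable yield of the field",
    "surface_residue", "kg/ha", "surface residue at v5",
    "soil_n_v5", "kg N/ha", "mineral soil N 0-60 cm at v5",
    "esw_v5", "mm", "extractable soil water at v5",
    "lai_v5", "-", "leaf area index at v5",
    "rain_to_v5", "mm", "rainfall up to v5",
    "temp_to_v5", "degree-days", "thermal time up to v5",
    "rad_to_v5", "MJ/m2", "radiation up to v5"
  )
}
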