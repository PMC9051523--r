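#' Generate the static field population
#'
#' Creates one row per field with region, role (trial vs evaluation), soil
#' attributes and long-term attainable yield. Regions are assigned by the
#' configured proportions with identical proportions in both roles, so trial
#' fields are interleaved with evaluation fields across the region gradient.
#' Soil organic matter and attainable yield means rise south to north.
#'
#' @param config an [synth_config()] object.
#' @return a tibble with columns `field_id`, `region`, `role`, `rotation_phase`
#'   (0/1: maize on even/odd year indices), `som` (%), `sand` (%), `clay` (%),
#'   `whc` (mm), `long_term_yield` (kg grain/ha).
#' @export
generate_sites <- function(config) {
  validate_synth_config(config)
  n_by_region <- function(n) {
    p <- config$region_props[REGIONS]
    p[is.na(p)] <- 0
    base <- floor(p * n)
    rem <- n - sum(base)
    frac <- p * n - base
    add <- head(order(frac, decreasing = TRUE), rem)
    base[add] <- base[add] + 1
    setNames(as.integer(base), REGIONS)
  }
  roles <- tibble::tibble(
    role = c(rep("trial", config$n_trial), rep("evaluation", config$n_eval)),
    region = c(rep(REGIONS, times = n_by_region(config$n_trial)),
               rep(REGIONS, times = n_by_region(config$n_eval)))
  )
  # interleave roles along the region gradient, then label ids in that order
  roles <- dplyr::arrange(roles, factor(.data$region, levels = REGIONS),
                          .data$role)
  roles$field_id <- seq_len(nrow(roles))
  # equal rotation halves: alternate phase in id order within each role
  roles <- roles %>%
    dplyr::group_by(.data$role) %>%
    dplyr::mutate(rotation_phase = (dplyr::row_number() - 1L) %% 2L) %>%
    dplyr::ungroup()

  draws <- purrr::map(seq_len(nrow(roles)), function(i) {
    fid <- roles$field_id[i]
    region <- roles$region[i]
    with_substream(config$seed, 1L, fid, expr = {
      z <- rnorm(4)
      som <- config$som_mean[[region]] + config$som_sd * z[1]
      sand <- runif(1, 8, 45)
      clay <- runif(1, 12, 35)
      whc <- 150 + 20 * som + 1.5 * clay - 0.5 * sand + 12 * z[2]
      lty <- config$yield_potential_mean[[region]] +
        config$yield_potential_sd * z[3]
      tibble::tibble(
        som = max(som, 0.4),
        sand = sand, clay = clay,
        whc = min(max(whc, 80), 400),
        long_term_yield = max(lty, 6000)
      )
    })
  })
  out <- dplyr::bind_cols(
    roles[c("field_id", "region", "role", "rotation_phase")],
    dplyr::bind_rows(draws)
  )
  dplyr::arrange(out, .data$field_id)
}

#' Generate the shared weather-year table
#'
#' One row per year, identical for all fields: the year is the blocking factor
#' of the leave-one-year-out evaluation. Early-season (to growth stage v5)
#' rainfall, temperature and radiation are observable covariates; the latent
#' `season_quality` (multiplier on attainable yield), `mineral_factor`
#' (multiplier on soil N supply) and `leach_season` (multiplier on baseline
#' leaching) are generator internals driven by the same draws, which is what
#' makes the observable weather informative.
#'
#' @inheritParams generate_sites
#' @return a tibble with one row per year.
#' @export
generate_weather <- function(config) {
  validate_synth_config(config)
  purrr::map_dfr(seq_len(config$n_years), function(yi) {
    with_substream(config$seed, 2L, yi, expr = {
      z <- rnorm(3)
      tibble::tibble(
        year = config$start_year + yi - 1L,
        rain_to_v5 = 300 * exp(0.25 * z[1]),
        temp_to_v5 = 950 + 80 * z[2],
        rad_to_v5 = 1150 + 90 * z[3],
        season_quality = exp(0.06 * z[2] + 0.04 * z[3]),
        mineral_factor = exp(0.10 * z[2] + 0.08 * z[1]),
        leach_season = exp(config$leach_rain_coef * z[1])
      )
    })
  })
}

# latent response-curve parameters and v5 covariates for every maize year of
# one field; one child RNG stream per field
field_year_params <- function(site, weather, config) {
  yi_all <- seq_len(config$n_years)
  maize <- yi_all[(yi_all - 1L) %% 2L == site$rotation_phase]
  n_my <- length(maize)
  if (n_my == 0L) return(NULL)
  w <- weather[maize, ]
  with_substream(config$seed, 3L, site$field_id, expr = {
    z <- matrix(rnorm(n_my * 8L), nrow = n_my)
    n_soil <- config$mineralization_rate * site$som * w$mineral_factor *
      exp(config$mineralization_sdlog * z[, 1] -
            config$mineralization_sdlog^2 / 2)
    y_att <- site$long_term_yield * w$season_quality *
      exp(config$yield_noise_sdlog * z[, 2] - config$yield_noise_sdlog^2 / 2)
    n_vertex <- pmin(pmax(config$n_vertex_mean + config$n_vertex_sd * z[, 3],
                          150), 350)
    l_base <- config$leach_base_rate * site$som * w$leach_season *
      exp(config$leach_base_sdlog * z[, 4] - config$leach_base_sdlog^2 / 2)
    l_slope <- config$leach_rate_coef * (site$som / 3)^config$leach_som_exp
    tibble::tibble(
      field_id = site$field_id,
      year = w$year,
      region = site$region,
      role = site$role,
      n_soil = n_soil, y_att = y_att, n_vertex = n_vertex, l_base = l_base,
      l_slope = l_slope,
      surface_residue = 0.35 * site$long_term_yield * exp(0.15 * z[, 5]),
      soil_n_v5 = n_soil * exp(0.12 * z[, 6]),
      esw_v5 = site$whc *
        (0.35 + 0.35 * stats::plogis((w$rain_to_v5 - 300) / 80)) *
        exp(0.08 * z[, 7]),
      lai_v5 = 1.3 * (y_att / 12600) * exp(0.10 * z[, 8]),
      whc = site$whc, som = site$som, sand = site$sand, clay = site$clay,
      rain_to_v5 = w$rain_to_v5, temp_to_v5 = w$temp_to_v5,
      rad_to_v5 = w$rad_to_v5,
      long_term_yield = site$long_term_yield
    )
  })
}

#' Quadratic-plateau yield / convex leaching curve family
#'
#' Evaluates tabulated yield and 2-year leaching over the N grid from the
#' latent field-year parameters. Yield follows a quadratic rise in total
#' plant-available N (fertilizer + soil supply) that plateaus at the attainable
#' yield; equivalently `Y(N) = min(Ymax, Y0 + s N - q N^2)` with field-year
#' specific coefficients. Leaching is the sum of a baseline term (soil organic
#' matter mineralization, present at N = 0), a softplus-convex rate-driven term
#' that accelerates once fertilizer N approaches the crop's demand, and a
#' soybean-year carryover proportional to the maize-year N surplus. A running
#' maximum over the grid keeps the carryover non-decreasing, so total leaching
#' is strictly increasing in N.
#'
#' @param params a tibble of latent parameters (one row per field-year) with
#'   columns `n_soil`, `y_att`, `n_vertex`, `l_base`.
#' @param config an [synth_config()] object (grid and shape constants).
#' @return a long tibble: one row per field-year x grid point with `n_rate`,
#'   `yield`, `leach2`.
#' @export
curve_family_quad_plateau <- function(params, config) {
  grid <- config$n_grid
  long <- tidyr::crossing(
    dplyr::select(params, "field_id", "year", "region", "role",
                  "n_soil", "y_att", "n_vertex", "l_base", "l_slope"),
    n_rate = grid
  )
  long <- long %>%
    dplyr::mutate(
      n_eff = pmin(.data$n_rate + .data$n_soil, .data$n_vertex),
      yield = .data$y_att * (1 - (1 - .data$n_eff / .data$n_vertex)^2),
      onset = .data$n_vertex - .data$n_soil - config$leach_onset_offset,
      rate_term = .data$l_slope * config$leach_rate_scale *
        softplus((.data$n_rate - .data$onset) / config$leach_rate_scale),
      surplus = pmax(0, .data$n_rate - config$grain_n_conc * .data$yield)
    ) %>%
    dplyr::arrange(.data$field_id, .data$year, .data$n_rate) %>%
    dplyr::group_by(.data$field_id, .data$year) %>%
    dplyr::mutate(leach2 = .data$l_base + .data$rate_term +
                    config$soy_carryover_frac * cummax(.data$surplus)) %>%
    dplyr::ungroup()
  dplyr::select(long, "field_id", "year", "region", "role", "n_rate",
                "yield", "leach2")
}

#' Generate one N response curve for a field-year
#'
#' The single-curve form of the generator: returns the tabulated yield and
#' 2-year leaching response of `site` in the season `year`, identical to the
#' corresponding rows of [generate_dataset()].
#'
#' @param site one row of [generate_sites()].
#' @param season one row of [generate_weather()] (the `year` selects the
#'   field-year; the field must crop maize that year).
#' @param config the same [synth_config()] both tables were generated under.
#' @return a list with `curve` (long tibble over the N grid) and `covariates`
#'   (one-row tibble of v5 predictors).
#' @export
generate_response_curve <- function(site, season, config) {
  weather <- generate_weather(config)
  params <- field_year_params(site, weather, config)
  if (is.null(params) || !season$year %in% params$year) {
    abort(sprintf("field %d does not crop maize in year %d",
                  site$field_id, season$year),
          class = "nfp_data_error")
  }
  params <- params[params$year == season$year, ]
  list(
    curve = curve_family_quad_plateau(params, config),
    covariates = dplyr::select(params, -dplyr::all_of(
      c("n_soil", "y_att", "n_vertex", "l_base", "l_slope")))
  )
}

#' Generate a complete synthetic dataset
#'
#' Builds the full field population, the shared weather years and, for every
#' field's maize years under the alternating maize-soybean rotation, the
#' tabulated N response curves and v5 covariates. Everything is determined by
#' `config$seed`.
#'
#' @inheritParams generate_sites
#' @return an object of class `nfp_dataset`: a list with tibbles `sites`,
#'   `weather`, `curves` (long: field x year x N rate), `covariates` (one row
#'   per field-year), `params` (latent generator parameters, for diagnostics)
#'   and the `config`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_trial = 4, n_eval = 6, n_years = 4))
#' dplyr::count(ds$curves, field_id, year)
generate_dataset <- function(config) {
  validate_synth_config(config)
  sites <- generate_sites(config)
  weather <- generate_weather(config)
  params <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    field_year_params(sites[i, ], weather, config)
  })
  family <- switch(config$curve_family,
    quad_plateau = curve_family_quad_plateau,
    abort(sprintf("unknown curve family '%s'", config$curve_family),
          class = "nfp_config_error")
  )
  curves <- family(params, config)
  covariates <- dplyr::select(params, -dplyr::all_of(
    c("n_soil", "y_att", "n_vertex", "l_base")))
  structure(
    list(sites = sites, weather = weather, curves = curves,
         covariates = covariates,
         params = dplyr::select(params, "field_id", "year", "region", "role",
                                "n_soil", "y_att", "n_vertex", "l_base",
                                "l_slope"),
         config = config),
    class = "nfp_dataset"
  )
}

#' @export
print.nfp_dataset <- function(x, ...) {
  cat("<nfp_dataset>", nrow(x$sites), "fields x", nrow(x$weather), "years:",
      nrow(x$covariates), "response curves on a",
      length(x$config$n_grid), "point N grid\n")
  invisible(x)
}

#' Names of the v5 predictor columns
#'
#' The early-season covariates available to the recommendation stage at the
#' maize v5 decision point.
#' @return a character vector.
#' @export
v5_covariates <- function() {
  c("surface_residue", "soil_n_v5", "esw_v5", "lai_v5", "whc", "som", "sand",
    "clay", "rain_to_v5", "temp_to_v5", "rad_to_v5", "long_term_yield")
}
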