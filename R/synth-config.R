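#' Configuration for the synthetic field population generator
#'
#' Defines the statistical structure of the simulated maize-soybean field
#' population: how many trial and evaluation fields, how many weather years,
#' the south-to-north regional gradients (soil organic matter and attainable
#' yield rise, baseline leaching rises, the economically optimal N rate falls),
#' and the distributional parameters of the yield and leaching response-curve
#' family. The same seed always reproduces the same dataset; per-field and
#' per-year child RNG streams are derived by counter, so changing one count
#' does not reshuffle unrelated draws.
#'
#' @param n_trial number of trial fields (must be even: the maize-soybean
#'   rotation splits them into two equal halves cropping maize in alternating
#'   years).
#' @param n_eval number of evaluation fields.
#' @param n_years number of weather years shared by all fields.
#' @param preset `"test"` (24 trial + 120 evaluation fields, 10 years; the
#'   default scale) or `"full"` (240 + 4,030 fields, 30 years, the
#'   published-study scale). Explicit arguments override the preset.
#' @param region_props named proportions of fields per region
#'   (south/central/north); must sum to 1.
#' @param start_year first calendar year label.
#' @param som_mean,som_sd regional mean and within-region s.d. of soil organic
#'   matter (%). Means must strictly increase south to north.
#' @param yield_potential_mean,yield_potential_sd regional mean and
#'   within-region s.d. of long-term attainable grain yield (kg/ha); means
#'   strictly increase south to north.
#' @param yield_noise_sdlog lognormal s.d. of the per-field-year multiplicative
#'   noise on attainable yield.
#' @param n_vertex_mean,n_vertex_sd total plant-available N (fertilizer + soil
#'   supply, kg N/ha) at which the quadratic yield response plateaus.
#' @param mineralization_rate kg N of seasonal soil supply per % soil organic
#'   matter at an average season.
#' @param mineralization_sdlog lognormal field-year noise on soil N supply.
#' @param leach_base_rate kg N/ha of baseline (zero-fertilizer) 2-year leaching
#'   per % soil organic matter.
#' @param leach_base_sdlog lognormal field noise on baseline leaching.
#' @param leach_rain_coef sensitivity of the leaching season factor to spring
#'   rainfall (on the log scale).
#' @param leach_rate_coef marginal kg N leached per kg fertilizer N once the
#'   rate-driven term is fully engaged (the softplus slope limit), for a field
#'   at the reference 3% soil organic matter.
#' @param leach_som_exp exponent scaling the marginal leaching slope with
#'   `(som / 3)`: wetter, high-mineralization soils lose a larger share of
#'   marginal fertilizer N, which concentrates rate-driven leaching (and
#'   policy-induced reductions) on high-leaching fields.
#' @param leach_rate_scale softness (kg N/ha) of the leaching onset.
#' @param leach_onset_offset kg N/ha below the yield plateau at which
#'   rate-driven leaching starts to accelerate.
#' @param soy_carryover_frac fraction of the maize-year N surplus
#'   (fertilizer minus grain removal) carried into the soybean-year leaching.
#' @param grain_n_conc grain N concentration (kg N per kg grain) used for the
#'   surplus carryover.
#' @param n_grid ordered vector of admissible N rates (kg N/ha).
#' @param curve_family response-curve family; `"quad_plateau"` is the only
#'   built-in (quadratic-plateau yield, softplus-convex leaching), but any
#'   function with the same signature can be supplied via
#'   [curve_family_quad_plateau()]'s contract.
#' @param seed integer root seed; fully determines every generated value.
#'
#' @return an object of class `nfp_config` (a validated list).
#' @seealso [generate_dataset()], [generate_sites()]
#' @export
#' @examples
#' cfg <- synth_config(n_trial = 4, n_eval = 8, n_years = 4, seed = 1)
#' cfg$n_trial
synth_config <- function(n_trial = NULL, n_eval = NULL, n_years = NULL,
                         preset = c("test", "full"),
                         region_props = c(south = 1 / 3, central = 1 / 3,
                                          north = 1 / 3),
                         start_year = 1989,
                         som_mean = c(south = 1.8, central = 3.0, north = 4.2),
                         som_sd = 0.4,
                         yield_potential_mean = c(south = 12600,
                                                  central = 13100,
                                                  north = 13800),
                         yield_potential_sd = 450,
                         yield_noise_sdlog = 0.13,
                         n_vertex_mean = 250, n_vertex_sd = 12,
                         mineralization_rate = 18,
                         mineralization_sdlog = 0.10,
                         leach_base_rate = 8,
                         leach_base_sdlog = 0.25,
                         leach_rain_coef = 0.30,
                         leach_rate_coef = 0.25,
                         leach_som_exp = 1.5,
                         leach_rate_scale = 25,
                         leach_onset_offset = 60,
                         soy_carryover_frac = 0.3,
                         grain_n_conc = 0.0115,
                         n_grid = seq(0, 320, by = 10),
                         curve_family = "quad_plateau",
                         seed = 1L) {
  preset <- match.arg(preset)
  scale <- switch(preset,
    test  = list(n_trial = 24L, n_eval = 120L, n_years = 10L),
    full = list(n_trial = 240L, n_eval = 4030L, n_years = 30L)
  )
  cfg <- list(
    preset = preset,
    n_trial = as.integer(n_trial %||% scale$n_trial),
    n_eval = as.integer(n_eval %||% scale$n_eval),
    n_years = as.integer(n_years %||% scale$n_years),
    region_props = region_props,
    start_year = as.integer(start_year),
    som_mean = som_mean, som_sd = som_sd,
    yield_potential_mean = yield_potential_mean,
    yield_potential_sd = yield_potential_sd,
    yield_noise_sdlog = yield_noise_sdlog,
    n_vertex_mean = n_vertex_mean, n_vertex_sd = n_vertex_sd,
    mineralization_rate = mineralization_rate,
    mineralization_sdlog = mineralization_sdlog,
    leach_base_rate = leach_base_rate,
    leach_base_sdlog = leach_base_sdlog,
    leach_rain_coef = leach_rain_coef,
    leach_rate_coef = leach_rate_coef,
    leach_som_exp = leach_som_exp,
    leach_rate_scale = leach_rate_scale,
    leach_onset_offset = leach_onset_offset,
    soy_carryover_frac = soy_carryover_frac,
    grain_n_conc = grain_n_conc,
    n_grid = sort(unique(as.numeric(n_grid))),
    curve_family = curve_family,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "nfp_config")
}

validate_synth_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid synthetic config: `%s` %s", field, why),
          class = "nfp_config_error")
  }
  if (is.na(cfg$n_trial) || cfg$n_trial < 2) bad("n_trial", "must be >= 2")
  if (cfg$n_trial %% 2L != 0L) {
    bad("n_trial", "must be even (rotation halves must be equal)")
  }
  if (is.na(cfg$n_eval) || cfg$n_eval < 2) bad("n_eval", "must be >= 2")
  if (is.na(cfg$n_years) || cfg$n_years < 2) bad("n_years", "must be >= 2")
  rp <- cfg$region_props
  if (is.null(names(rp)) || !all(names(rp) %in% REGIONS)) {
    bad("region_props", "must be named with south/central/north")
  }
  if (any(rp < 0) || abs(sum(rp) - 1) > 1e-8) {
    bad("region_props", "must be non-negative and sum to 1")
  }
  for (f in c("som_mean", "yield_potential_mean")) {
    v <- cfg[[f]]
    if (!all(REGIONS %in% names(v))) bad(f, "needs south/central/north entries")
    v <- v[REGIONS]
    if (!(v[1] < v[2] && v[2] < v[3])) {
      bad(f, "must strictly increase south -> central -> north")
    }
  }
  if (any(cfg$som_mean <= 0)) bad("som_mean", "must be positive")
  for (f in c("som_sd", "yield_potential_sd", "yield_noise_sdlog",
              "n_vertex_mean", "n_vertex_sd", "mineralization_rate",
              "mineralization_sdlog", "leach_base_rate", "leach_base_sdlog",
              "leach_rate_coef", "leach_som_exp", "leach_rate_scale")) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0)) bad(f, "must be >= 0")
  }
  if (cfg$soy_carryover_frac < 0 || cfg$soy_carryover_frac > 1) {
    bad("soy_carryover_frac", "must be in [0, 1]")
  }
  if (cfg$grain_n_conc <= 0 || cfg$grain_n_conc >= 0.05) {
    bad("grain_n_conc", "must be in (0, 0.05)")
  }
  g <- cfg$n_grid
  if (length(g) < 2 || g[1] != 0 || max(g) < 320) {
    bad("n_grid", "must cover 0 to 320 inclusive")
  }
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.nfp_config <- function(x, ...) {
  cat("<nfp_config>", x$preset, "preset:",
      x$n_trial, "trial +", x$n_eval, "evaluation fields,",
      x$n_years, "years, seed", x$seed, "\n")
  invisible(x)
}
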