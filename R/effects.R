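#' Cost-efficiency curve of a policy sweep
#'
#' State-scope pairs of N-leaching reduction (% of base) and policy cost
#' (US$/ha), ordered by sub-level; sub-levels excluded by the yield guard are
#' dropped. The base point is (0, 0).
#'
#' @param sweep an [run_sweep()] object, or its `summaries` tibble (must
#'   include the base row).
#' @return a tibble: `policy`, `sublevel`, `leach2`, `reduction_pct`,
#'   `policy_cost`.
#' @export
cost_efficiency_curve <- function(sweep) {
  summaries <- if (inherits(sweep, "nfp_sweep")) sweep$summaries else sweep
  st <- dplyr::filter(summaries, .data$scope == "state")
  base <- dplyr::filter(st, .data$policy == "base")
  if (nrow(base) != 1) {
    abort("sweep summaries must contain exactly one base state row",
          class = "nfp_data_error")
  }
  st %>%
    dplyr::filter(.data$policy != "base", !.data$excluded) %>%
    dplyr::arrange(.data$sublevel) %>%
    dplyr::transmute(
      policy = .data$policy,
      sublevel = .data$sublevel,
      leach2 = .data$leach2,
      reduction_pct = 100 * (base$leach2 - .data$leach2) / base$leach2,
      policy_cost = .data$policy_cost
    ) %>%
    tibble::add_row(policy = base$policy, sublevel = NA_real_,
                    leach2 = base$leach2, reduction_pct = 0, policy_cost = 0,
                    .before = 1)
}

#' Select the sub-level achieving a target state leaching reduction
#'
#' Returns the smallest swept sub-level whose state-wise reduction meets the
#' target, together with a linearly interpolated sub-level between the
#' bracketing grid points.
#'
#' @param sweep an [run_sweep()] object or summaries tibble.
#' @param target_reduction target reduction in state N leaching, percent.
#' @return a one-row tibble: `policy`, `target_reduction`, `sublevel_grid`,
#'   `achieved_grid` (reduction at that grid sub-level), `sublevel_interp`.
#' @export
select_sublevel <- function(sweep, target_reduction = 20) {
  curve <- cost_efficiency_curve(sweep)
  pol <- curve$policy[curve$policy != "base"][1]
  curve <- dplyr::filter(curve, .data$policy == pol)
  if (target_reduction <= 0) {
    base_sub <- curve$sublevel[which.min(abs(curve$reduction_pct))]
    return(tibble::tibble(policy = pol, target_reduction = target_reduction,
                          sublevel_grid = base_sub, achieved_grid = 0,
                          sublevel_interp = base_sub))
  }
  hit <- which(curve$reduction_pct >= target_reduction)
  if (length(hit) == 0) {
    abort(sprintf(
      "target %.3g%% unreachable within the sweep (max achieved %.3g%%)",
      target_reduction, max(curve$reduction_pct)),
      class = "nfp_data_error")
  }
  i <- min(hit)
  sub_grid <- curve$sublevel[i]
  interp <- if (i == 1 || is.na(curve$sublevel[i - 1])) {
    sub_grid
  } else {
    approx(x = curve$reduction_pct[(i - 1):i],
           y = curve$sublevel[(i - 1):i],
           xout = target_reduction, ties = "ordered")$y
  }
  tibble::tibble(policy = pol, target_reduction = target_reduction,
                 sublevel_grid = sub_grid,
                 achieved_grid = curve$reduction_pct[i],
                 sublevel_interp = interp)
}

#' Own-price (arc) elasticity of N fertilizer demand
#'
#' Arc elasticity with the midpoint convention:
#' `|dQ / mean(Q)| / |dP / mean(P)|`, computed from the state mean fertilizer
#' N at two price-ratio sub-levels (the N price is `ratio * p_maize`).
#'
#' @param n_demand length-2 numeric: state mean N rate at the two sub-levels.
#' @param ratios length-2 numeric: the two N:maize price ratios.
#' @return a non-negative unitless elasticity (0 for flat demand).
#' @export
#' @examples
#' own_price_elasticity(c(100, 50), c(1, 2))  # 1: N halves as price doubles
own_price_elasticity <- function(n_demand, ratios) {
  stopifnot(length(n_demand) == 2, length(ratios) == 2)
  dq <- diff(n_demand) / mean(n_demand)
  dp <- diff(ratios) / mean(ratios)
  if (dp == 0) abort("the two price ratios must differ",
                     class = "nfp_domain_error")
  abs(dq / dp)
}

#' Field-level effect regressions (income, point-source, internalization)
#'
#' Fits three OLS regressions on field-level values averaged across years:
#' income effect (farm profits + compensation vs base income), point source
#' reduction effect (N leaching vs base leaching; slope < 1 means reductions
#' concentrate on high-leaching fields), internalization effect (profit change
#' vs base leaching; negative slope means the policy charges fields with high
#' environmental cost). Slope p-values are two-sided t-tests; stars follow
#' *p<0.1, **p<0.05, ***p<0.01.
#'
#' @param outcomes,base_outcomes matched [evaluate_fields()] tables.
#' @param plan the [compensate()] plan of the run (per-region lump sums).
#' @param policy_kind label carried into the output.
#' @return a tibble of class `nfp_effects`: one row per effect with `slope`,
#'   `p_value`, `r_squared`, `stars`, `n_fields`.
#' @export
field_effects <- function(outcomes, base_outcomes, plan,
                          policy_kind = "policy") {
  per_field <- function(x, cols) {
    x %>%
      dplyr::group_by(.data$region, .data$field_id) %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       .groups = "drop")
  }
  pol <- per_field(outcomes, c("profit_after", "leach2")) %>%
    dplyr::left_join(dplyr::select(plan, "region", "total_per_ha"),
                     by = "region") %>%
    dplyr::mutate(income = .data$profit_after + .data$total_per_ha)
  base <- per_field(base_outcomes, c("profit_after", "leach2")) %>%
    dplyr::rename(base_profit = "profit_after", base_leach2 = "leach2")
  d <- dplyr::inner_join(pol, base, by = c("region", "field_id"))
  fits <- list(
    income = lm(income ~ base_profit, data = d),
    point_source = lm(leach2 ~ base_leach2, data = d),
    internalization = lm(I(profit_after - base_profit) ~ base_leach2,
                         data = d)
  )
  out <- purrr::imap_dfr(fits, function(fit, nm) {
    s <- slope_stats(fit)
    tibble::tibble(policy = policy_kind, effect = nm, slope = s$slope,
                   p_value = s$p, r_squared = s$r2, stars = p_stars(s$p),
                   n_fields = nrow(d))
  })
  class(out) <- c("nfp_effects", class(out))
  out
}

#' N balance vs N leaching diagnostic across dataset complexities
#'
#' Reproduces the classic diagnostic of the N-balance surplus indicator: its
#' association with leaching is strong when leaching variation is rate-driven
#' (one or few locations, several fixed N rates) and collapses when variation
#' comes from soils and weather (many locations at a common rate, or at
#' recommended rates). Five scenarios: (A) 1 location x 4 fixed rates, (B) 45
#' locations x 4 fixed rates, (C) many locations at one common fixed rate,
#' (D) 45 locations at the recommender's base-level rates, (E) all (up to
#' 5,000) locations at recommended rates. Scenario sizes shrink automatically
#' on small datasets. Locations are field-years sampled with a seeded RNG.
#'
#' @param dataset an [generate_dataset()] object.
#' @param base_outcomes base-level [evaluate_fields()] outcomes (supply the
#'   recommended-rate scenarios D and E).
#' @param fixed_rates four N rates (on the grid) for scenarios A and B.
#' @param common_rate single N rate for scenario C.
#' @param n_locations named sizes for scenarios B:E.
#' @param seed sampling seed.
#' @param grain_n_conc grain N concentration for the balance.
#' @return a tibble of class `nfp_balance_diag`: one row per scenario with
#'   `slope`, `p_value`, `r_squared`, `n`; degenerate scenarios (no variance)
#'   return missing values with a warning. The sampled points are attached as
#'   attribute `"points"` for plotting.
#' @export
n_balance_diagnostic <- function(dataset, base_outcomes,
                                 fixed_rates = c(0, 110, 220, 320),
                                 common_rate = 180,
                                 n_locations = c(B = 45, C = 5000, D = 45,
                                                 E = 5000),
                                 seed = 1L, grain_n_conc = 0.0115) {
  curves <- dataset$curves
  locs <- dplyr::distinct(curves, .data$field_id, .data$year)
  take <- function(n) {
    n <- min(n, nrow(locs))
    with_substream(seed, 7L, n, expr = locs[sample(nrow(locs), n), ])
  }
  at_rates <- function(loc, rates) {
    dplyr::inner_join(curves, loc, by = c("field_id", "year")) %>%
      dplyr::filter(.data$n_rate %in% rates) %>%
      dplyr::mutate(n_balance = n_balance(.data$n_rate, .data$yield,
                                          grain_n_conc))
  }
  scenarios <- list(
    A = at_rates(take(1), fixed_rates),
    B = at_rates(take(n_locations[["B"]]), fixed_rates),
    C = at_rates(take(n_locations[["C"]]), common_rate),
    D = dplyr::semi_join(base_outcomes, take(n_locations[["D"]]),
                         by = c("field_id", "year")),
    E = dplyr::semi_join(base_outcomes, take(n_locations[["E"]]),
                         by = c("field_id", "year"))
  )
  desc <- c(A = "1 location x 4 fixed rates",
            B = "45 locations x 4 fixed rates",
            C = "many locations, one common rate",
            D = "45 locations at recommended rates",
            E = "all locations at recommended rates")
  out <- purrr::imap_dfr(scenarios, function(d, nm) {
    res <- if (nrow(d) < 3 || stats::var(d$n_balance) == 0) {
      warn(sprintf("scenario %s is degenerate (no N-balance variance)", nm))
      list(slope = NA_real_, p = NA_real_, r2 = NA_real_)
    } else {
      slope_stats(lm(leach2 ~ n_balance, data = d))
    }
    tibble::tibble(scenario = nm, description = unname(desc[nm]),
                   slope = res$slope, p_value = res$p, r_squared = res$r2,
                   stars = p_stars(res$p), n = nrow(d))
  })
  attr(out, "points") <- purrr::imap_dfr(scenarios, function(d, nm) {
    dplyr::transmute(d, scenario = nm, n_balance = .data$n_balance,
                     leach2 = .data$leach2)
  })
  class(out) <- c("nfp_balance_diag", class(out))
  out
}

#' Welfare accounting for a state-scale leaching reduction
#'
#' Scales a per-hectare leaching reduction and policy cost to the state maize
#' area, prices the avoided leaching at the externality cost of groundwater
#' contamination, and reports the welfare gain (externality reduction minus
#' policy cost) and return on investment. Identity:
#' `welfare_gain + policy_cost_total = externality_reduction`, exactly.
#'
#' @param delta_leach_per_ha avoided 2-year N leaching, kg N/ha (base minus
#'   policy).
#' @param policy_cost_per_ha deadweight cost of the policy, US$/ha. Exactly
#'   one of `policy_cost_per_ha` / `policy_cost_total` must be given.
#' @param policy_cost_total total yearly policy cost, US$/yr.
#' @param externality_cost_per_kg monetized damage per kg N leached
#'   (default 16.1 US$/kg).
#' @param state_area maize area scaled to, ha (default 4.4 million).
#' @return an object of class `nfp_welfare` (see [tidy.nfp_welfare()]).
#' @export
#' @examples
#' welfare(delta_leach_per_ha = 7.4, policy_cost_per_ha = 33.75)
welfare <- function(delta_leach_per_ha, policy_cost_per_ha = NULL,
                    policy_cost_total = NULL,
                    externality_cost_per_kg = 16.1, state_area = 4.4e6) {
  if (is.null(policy_cost_total) == is.null(policy_cost_per_ha)) {
    abort("give exactly one of policy_cost_per_ha / policy_cost_total",
          class = "nfp_domain_error")
  }
  if (is.null(policy_cost_total)) {
    policy_cost_total <- policy_cost_per_ha * state_area
  }
  load_reduction <- delta_leach_per_ha * state_area
  externality_reduction <- load_reduction * externality_cost_per_kg
  welfare_gain <- externality_reduction - policy_cost_total
  roi <- if (policy_cost_total > 0) {
    100 * welfare_gain / policy_cost_total
  } else {
    NA_real_
  }
  structure(list(
    externality_cost_per_kg = externality_cost_per_kg,
    state_area = state_area,
    load_reduction = load_reduction,
    externality_reduction = externality_reduction,
    policy_cost_total = policy_cost_total,
    welfare_gain = welfare_gain,
    roi = roi
  ), class = "nfp_welfare")
}

#' @export
print.nfp_welfare <- function(x, ...) {
  cat(sprintf(
    "<nfp_welfare> load -%.3g Mkg/yr, externality -%.4g M US$/yr,\n  policy cost %.4g M US$/yr, welfare gain %.4g M US$/yr (ROI %s%%)\n",
    x$load_reduction / 1e6, x$externality_reduction / 1e6,
    x$policy_cost_total / 1e6, x$welfare_gain / 1e6,
    ifelse(is.na(x$roi), "NA", sprintf("%.0f", x$roi))))
  invisible(x)
}
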