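#' Realized field outcomes at the recommended rates
#'
#' Looks up yield and 2-year leaching of each evaluation field-year at its
#' recommended N rate and computes the economic decomposition: grain revenue,
#' fertilizer cost (including any price-ratio tax), fee paid (leaching or
#' balance fee), profit after all taxes and fees (before compensation), the
#' N balance, and the per-hectare government collection generated by the field
#' (the tax wedge `(p_n' - p_n) * N` under the price-ratio policy, the fee
#' under fee policies, zero otherwise). Every field represents 1 ha.
#'
#' @param curves long response-curve table restricted to the field-years being
#'   evaluated.
#' @param rates tibble with `field_id`, `year`, `n_rate` (on the grid), e.g.
#'   from [recommend()].
#' @param policy,prices the policy instrument and market prices.
#' @return a tibble, one row per field-year, class `tbl_df`.
#' @export
evaluate_fields <- function(curves, rates, policy,
                            prices = nfertpolicy::prices()) {
  rates <- dplyr::select(rates, "field_id", "year", "n_rate")
  joined <- dplyr::inner_join(curves, rates,
                              by = c("field_id", "year", "n_rate"))
  if (nrow(joined) != nrow(rates)) {
    missing <- dplyr::anti_join(rates, joined,
                                by = c("field_id", "year", "n_rate"))
    abort(sprintf(
      "%d recommended rate(s) not on the response-curve grid (first: field %s year %s rate %s)",
      nrow(missing), missing$field_id[1], missing$year[1], missing$n_rate[1]),
      class = "nfp_data_error")
  }
  out <- policy_profit(joined, policy, prices)
  wedge <- if (policy$kind == "price_ratio") {
    (effective_p_n(policy, prices) - prices$p_n)
  } else {
    0
  }
  out %>%
    dplyr::mutate(
      n_balance = n_balance(.data$n_rate, .data$yield, policy$grain_n_conc),
      collection = wedge * .data$n_rate + .data$fee_paid,
      profit_after = .data$profit
    ) %>%
    dplyr::select("field_id", "year", "region", "n_rate", "yield", "leach2",
                  "gross_revenue", "fert_cost", "fee_paid", "profit_after",
                  "n_balance", "collection")
}

# two-step mean: equal weight per year within field, then per field
field_then_region_mean <- function(outcomes, cols, scope = c("region", "state")) {
  scope <- match.arg(scope)
  per_field <- outcomes %>%
    dplyr::group_by(.data$region, .data$field_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  if (scope == "region") {
    per_field %>%
      dplyr::group_by(.data$region) %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       .groups = "drop")
  } else {
    per_field %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean)) %>%
      dplyr::mutate(region = "state", .before = 1)
  }
}

#' Government collections per region (and region-year)
#'
#' Funds transferred from farmers to the regulator: the price-ratio tax wedge
#' or the leaching/balance fees. Zero under the base and voluntary policies.
#' Fields are weighted equally (1 ha each).
#'
#' @param outcomes an [evaluate_fields()] table for one (policy, sublevel) run.
#' @return a list with `by_region_year` (mean collection per ha for each
#'   region-year) and `by_region` (two-step aggregated mean per region).
#' @export
government_collections <- function(outcomes) {
  by_ry <- outcomes %>%
    dplyr::group_by(.data$region, .data$year) %>%
    dplyr::summarise(collections_per_ha = mean(.data$collection),
                     n_fields = dplyr::n(), .groups = "drop")
  by_r <- field_then_region_mean(outcomes, "collection") %>%
    dplyr::rename(collections_per_ha = "collection")
  list(by_region_year = by_ry, by_region = by_r)
}

#' Two-component lump-sum compensation plan
#'
#' Component 1 returns the regional government collections as an equal
#' per-hectare payment; component 2 covers the policy cost, the residual drop
#' in regional mean income after collections are returned (the deadweight
#' loss). By construction the plan restores the regional mean income to its
#' base level; being lump-sum, it cannot distort an individual field's N-rate
#' choice. Under the voluntary policy component 1 is zero.
#'
#' @param outcomes,base_outcomes [evaluate_fields()] tables for the policy run
#'   and the matching base-level run (same fields and years).
#' @param policy the policy evaluated.
#' @return a tibble per region: `collections_per_ha`, `policy_cost_per_ha`,
#'   `total_per_ha` (US$/ha).
#' @export
compensate <- function(outcomes, base_outcomes, policy) {
  if (is.null(base_outcomes) || nrow(base_outcomes) == 0) {
    abort("a matching base-level run is required to compute compensation",
          class = "nfp_data_error")
  }
  pol <- field_then_region_mean(outcomes, c("profit_after", "collection"))
  base <- field_then_region_mean(base_outcomes, "profit_after") %>%
    dplyr::rename(base_profit = "profit_after")
  dplyr::inner_join(pol, base, by = "region") %>%
    dplyr::transmute(
      region = .data$region,
      collections_per_ha = .data$collection,
      policy_cost_per_ha = .data$base_profit -
        (.data$profit_after + .data$collection),
      total_per_ha = .data$collections_per_ha + .data$policy_cost_per_ha
    )
}

#' Aggregate field outcomes to Table-style policy summaries
#'
#' Produces one row per region plus a state row with the headline indicators:
#' yield (t/ha), 2-year leaching and fertilizer N (kg/ha), farm profits after
#' taxes/fees, government collections, policy cost, and the abatement cost
#' (policy cost per kg of leaching avoided relative to base; missing when no
#' leaching is avoided). Aggregation gives each year equal weight within a
#' field, then each field equal weight.
#'
#' @inheritParams compensate
#' @param policy the [policy()] the outcomes were generated under.
#' @return a tibble with `scope` ("region"/"state") and indicator columns.
#' @export
summarise_policy <- function(outcomes, base_outcomes = NULL,
                             policy = nfertpolicy::policy("base")) {
  cols <- c("yield", "leach2", "n_rate", "profit_after", "collection")
  agg <- dplyr::bind_rows(
    field_then_region_mean(outcomes, cols, "region"),
    field_then_region_mean(outcomes, cols, "state")
  )
  if (!is.null(base_outcomes)) {
    base_agg <- dplyr::bind_rows(
      field_then_region_mean(base_outcomes, c("leach2", "profit_after"),
                             "region"),
      field_then_region_mean(base_outcomes, c("leach2", "profit_after"),
                             "state")
    ) %>%
      dplyr::rename(base_leach2 = "leach2", base_profit = "profit_after")
    agg <- dplyr::inner_join(agg, base_agg, by = "region")
  } else {
    agg <- dplyr::mutate(agg, base_leach2 = NA_real_, base_profit = NA_real_)
  }
  kind <- policy$kind
  sub <- policy$sublevel
  agg %>%
    dplyr::transmute(
      scope = ifelse(.data$region == "state", "state", "region"),
      region = .data$region,
      policy = kind,
      sublevel = sub,
      yield_t_ha = .data$yield / 1000,
      leach2 = .data$leach2,
      n_fert = .data$n_rate,
      profits = .data$profit_after,
      gov_collections = .data$collection,
      policy_cost = .data$base_profit - (.data$profit_after + .data$collection),
      abatement_cost = dplyr::if_else(
        .data$base_leach2 - .data$leach2 > 0,
        .data$policy_cost / (.data$base_leach2 - .data$leach2),
        NA_real_),
      excluded = FALSE
    )
}

#' Flag policy sub-levels that breach the regional yield guard
#'
#' A (policy, sublevel) is excluded when its regional yield falls below 95% of
#' the base-level regional yield in any region (strict inequality: exactly 95%
#' is kept). Mirrors the assumption that larger production shocks would feed
#' back on prices, outside the model's scope.
#'
#' @param summaries stacked [summarise_policy()] rows for one or more
#'   sub-levels.
#' @param base_summaries the base-level [summarise_policy()] rows.
#' @param guard minimum retained fraction of base yield (default 0.95).
#' @return `summaries` with the `excluded` flag filled in.
#' @export
yield_guard <- function(summaries, base_summaries, guard = 0.95) {
  base <- base_summaries %>%
    dplyr::filter(.data$scope == "region") %>%
    dplyr::select("region", base_yield = "yield_t_ha")
  flags <- summaries %>%
    dplyr::filter(.data$scope == "region") %>%
    dplyr::inner_join(base, by = "region") %>%
    dplyr::group_by(.data$policy, .data$sublevel) %>%
    dplyr::summarise(
      excluded = any(.data$yield_t_ha < guard * .data$base_yield),
      .groups = "drop")
  summaries %>%
    dplyr::select(-"excluded") %>%
    dplyr::left_join(flags, by = c("policy", "sublevel")) %>%
    dplyr::mutate(excluded = dplyr::coalesce(.data$excluded, FALSE))
}
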