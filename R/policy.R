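#' Market prices for maize grain and fertilizer N
#'
#' The base situation uses 0.158 US$/kg maize and 0.79 US$/kg N, i.e. a price
#' ratio of 5 kg maize per kg N.
#'
#' @param p_maize price of maize grain, US$/kg.
#' @param p_n price of fertilizer N, US$/kg N.
#' @return an object of class `nfp_prices`.
#' @export
#' @examples
#' price_ratio(prices())  # 5
prices <- function(p_maize = 0.158, p_n = 0.79) {
  if (!is.numeric(p_maize) || !is.numeric(p_n) || p_maize <= 0 || p_n <= 0) {
    abort("prices must be positive numbers", class = "nfp_domain_error")
  }
  structure(list(p_maize = p_maize, p_n = p_n), class = "nfp_prices")
}

#' N:maize price ratio (kg maize per kg N)
#' @param prices an [prices()] object.
#' @return `p_n / p_maize`.
#' @export
price_ratio <- function(prices) {
  stopifnot(inherits(prices, "nfp_prices"))
  prices$p_n / prices$p_maize
}

policy_kinds <- c("base", "price_ratio", "leaching_fee", "balance_fee",
                  "voluntary")

sublevel_range <- list(
  base = c(NA_real_, NA_real_),
  price_ratio = c(5, 20),     # target ratio, kg maize/kg N
  leaching_fee = c(0, 40),    # US$/kg N leached above threshold
  balance_fee = c(0, 4),      # US$/kg N balance above threshold
  voluntary = c(0, 0.30)      # fraction of the base recommendation
)

#' Define a policy instrument
#'
#' One of five variants: the no-policy base level; an N price tax expressed as
#' a target N:maize price ratio; a fee per kg of 2-year N leaching above a
#' regional threshold; a fee per kg of N-balance surplus above a regional
#' threshold; or a voluntary fractional reduction from the base-level
#' recommendation. The fee policies require regional thresholds, normally
#' derived from a base-level run with [compute_thresholds()].
#'
#' @param kind one of `"base"`, `"price_ratio"`, `"leaching_fee"`,
#'   `"balance_fee"`, `"voluntary"`.
#' @param sublevel the policy's scalar severity: target ratio in `[5, 20]`,
#'   leaching fee in `[0, 40]` US$/kg, balance fee in `[0, 4]` US$/kg, or
#'   reduction fraction in `[0, 0.30]`.
#' @param leach_thresholds,balance_thresholds named per-region vectors
#'   (kg N/ha), required iff `kind` is the corresponding fee.
#' @param grain_n_conc grain N concentration (kg N/kg grain) for the balance.
#' @return an object of class `nfp_policy`.
#' @export
policy <- function(kind, sublevel = NULL, leach_thresholds = NULL,
                   balance_thresholds = NULL, grain_n_conc = 0.0115) {
  kind <- match.arg(kind, policy_kinds)
  if (kind == "base") {
    sublevel <- NA_real_
  } else {
    if (is.null(sublevel) || !is.numeric(sublevel) || length(sublevel) != 1) {
      abort(sprintf("policy '%s' needs a scalar sublevel", kind),
            class = "nfp_config_error")
    }
    rng <- sublevel_range[[kind]]
    if (sublevel < rng[1] || sublevel > rng[2]) {
      abort(sprintf("sublevel %.3g outside [%g, %g] for policy '%s'",
                    sublevel, rng[1], rng[2], kind),
            class = "nfp_config_error")
    }
  }
  check_thr <- function(thr, name, needed) {
    if (needed) {
      if (is.null(thr) || !all(REGIONS %in% names(thr))) {
        abort(sprintf("policy '%s' requires %s for all regions", kind, name),
              class = "nfp_config_error")
      }
    }
    thr
  }
  structure(list(
    kind = kind, sublevel = sublevel,
    leach_thresholds = check_thr(leach_thresholds, "leach_thresholds",
                                 kind == "leaching_fee"),
    balance_thresholds = check_thr(balance_thresholds, "balance_thresholds",
                                   kind == "balance_fee"),
    grain_n_conc = grain_n_conc
  ), class = "nfp_policy")
}

#' @export
print.nfp_policy <- function(x, ...) {
  cat("<nfp_policy>", x$kind,
      if (!is.na(x$sublevel)) paste("@", signif(x$sublevel, 4)), "\n")
  invisible(x)
}

#' N balance: fertilizer N minus grain N removal
#'
#' A surplus indicator (kg N/ha, may be negative): N applied as mineral
#' fertilizer minus the N harvested in maize grain, computed from yield and a
#' grain N concentration of 11.5 g N/kg grain by default.
#'
#' @param n_fert fertilizer N rate, kg N/ha.
#' @param yield grain yield, kg/ha.
#' @param grain_n_conc kg N per kg grain.
#' @return kg N/ha.
#' @export
#' @examples
#' n_balance(176, 12600)  # 31.1
n_balance <- function(n_fert, yield, grain_n_conc = 0.0115) {
  stopifnot(all(n_fert >= 0, na.rm = TRUE), all(yield >= 0, na.rm = TRUE))
  n_fert - yield * grain_n_conc
}

# effective N price after a price-ratio tax
effective_p_n <- function(policy, prices) {
  if (policy$kind == "price_ratio") policy$sublevel * prices$p_maize
  else prices$p_n
}

#' Policy-conditional profit decomposition on response-curve rows
#'
#' Adds the revenue/cost/fee/profit decomposition to a long response-curve
#' table (one row per field-year x N rate, with `region`, `n_rate`, `yield`,
#' `leach2` columns). Under the base and voluntary policies, profit is grain
#' revenue minus fertilizer cost; the price-ratio policy raises the effective
#' N price to `sublevel * p_maize`; the fee policies subtract
#' `fee * max(0, indicator - regional threshold)` where the indicator is the
#' 2-year leaching or the N balance.
#'
#' @param curves long response-curve tibble.
#' @param policy an [policy()] object.
#' @param prices an [prices()] object.
#' @return the input with added columns `gross_revenue`, `fert_cost`,
#'   `fee_paid`, `profit` (all US$/ha).
#' @export
policy_profit <- function(curves, policy, prices = nfertpolicy::prices()) {
  stopifnot(inherits(policy, "nfp_policy"), inherits(prices, "nfp_prices"))
  need <- c("n_rate", "yield", "leach2")
  miss <- setdiff(need, names(curves))
  if (length(miss) > 0) {
    abort(paste("curves table is missing columns:", toString(miss)),
          class = "nfp_data_error")
  }
  if (policy$kind %in% c("leaching_fee", "balance_fee") &&
      !"region" %in% names(curves)) {
    abort("fee policies need a `region` column on the curves table",
          class = "nfp_data_error")
  }
  p_n_eff <- effective_p_n(policy, prices)
  out <- dplyr::mutate(curves,
    gross_revenue = prices$p_maize * .data$yield,
    fert_cost = p_n_eff * .data$n_rate
  )
  fee <- switch(policy$kind,
    leaching_fee = {
      thr <- policy$leach_thresholds[out$region]
      policy$sublevel * pmax(0, out$leach2 - thr)
    },
    balance_fee = {
      thr <- policy$balance_thresholds[out$region]
      bal <- n_balance(out$n_rate, out$yield, policy$grain_n_conc)
      policy$sublevel * pmax(0, bal - thr)
    },
    0
  )
  dplyr::mutate(out,
    fee_paid = as.numeric(fee),
    profit = .data$gross_revenue - .data$fert_cost - .data$fee_paid
  )
}

#' Economically optimal N rate under a policy
#'
#' Selects, for every field-year curve, the grid N rate maximising the
#' policy-conditional profit; profit ties are broken toward the lowest rate.
#' The voluntary policy instead scales the base-level EONR by
#' `(1 - sublevel)` and snaps the result down to the grid.
#'
#' @inheritParams policy_profit
#' @return a tibble with one row per field-year: `field_id`, `year`, `eonr`
#'   (kg N/ha, on the grid).
#' @export
#' @examples
#' curve <- tibble::tibble(field_id = 1, year = 1, region = "south",
#'                         n_rate = c(0, 100, 200),
#'                         yield = c(5000, 9000, 9500), leach2 = c(10, 15, 30))
#' eonr(curve, policy("base"))
eonr <- function(curves, policy, prices = nfertpolicy::prices()) {
  if (policy$kind == "voluntary") {
    base <- eonr(curves, nfertpolicy::policy("base"), prices)
    grid <- sort(unique(curves$n_rate))
    return(dplyr::mutate(
      base, eonr = snap_to_grid((1 - policy$sublevel) * .data$eonr,
                                grid, mode = "down")))
  }
  policy_profit(curves, policy, prices) %>%
    dplyr::arrange(.data$field_id, .data$year, .data$n_rate) %>%
    dplyr::group_by(.data$field_id, .data$year) %>%
    dplyr::summarise(eonr = .data$n_rate[which.max(.data$profit)],
                     .groups = "drop")
}

#' Regional fee thresholds from a base-level run
#'
#' The leaching threshold of each region is 60% of the long-run mean 2-year
#' leaching at the base level; the balance threshold is the long-run mean base
#' N balance minus 60 kg/ha. Means follow the standard aggregation rule:
#' first across years within a field (equal year weights), then across fields
#' (equal field weights).
#'
#' @param base_outcomes per-field-year base-level outcomes with `region`,
#'   `field_id`, `year`, `leach2`, `n_balance` columns (see
#'   [evaluate_fields()]).
#' @param leach_frac fraction of mean base leaching retained as the free
#'   allowance (default 0.6).
#' @param balance_offset kg N/ha subtracted from the mean base balance.
#' @return a list with named per-region vectors `leach` and `balance`.
#' @export
compute_thresholds <- function(base_outcomes, leach_frac = 0.6,
                               balance_offset = 60) {
  present <- unique(base_outcomes$region)
  missing_regions <- setdiff(REGIONS, present)
  if (length(missing_regions) > 0) {
    abort(paste("no base-level outcomes for region(s):",
                toString(missing_regions)),
          class = "nfp_data_error")
  }
  means <- base_outcomes %>%
    dplyr::group_by(.data$region, .data$field_id) %>%
    dplyr::summarise(leach2 = mean(.data$leach2),
                     n_balance = mean(.data$n_balance), .groups = "drop") %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(leach2 = mean(.data$leach2),
                     n_balance = mean(.data$n_balance), .groups = "drop")
  list(
    leach = setNames(leach_frac * means$leach2, means$region)[REGIONS],
    balance = setNames(means$n_balance - balance_offset,
                       means$region)[REGIONS]
  )
}
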