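#' Plot the sub-level trajectories of a policy sweep
#'
#' Faceted trajectories of state-level fertilizer N use, 2-year leaching,
#' farm profits, government collections and policy cost against the policy
#' sub-level — the standard picture of how tightening an instrument moves the
#' system.
#'
#' @param sweep an [run_sweep()] object or its summaries tibble.
#' @return a ggplot.
#' @export
plot_sweep <- function(sweep) {
  summaries <- if (inherits(sweep, "nfp_sweep")) sweep$summaries else sweep
  st <- summaries %>%
    dplyr::filter(.data$scope == "state", .data$policy != "base") %>%
    dplyr::select("policy", "sublevel", "excluded",
                  `N fertilizer (kg/ha)` = "n_fert",
                  `N leaching (kg/ha)` = "leach2",
                  `Profits (US$/ha)` = "profits",
                  `Collections (US$/ha)` = "gov_collections",
                  `Policy cost (US$/ha)` = "policy_cost") %>%
    tidyr::pivot_longer(-c("policy", "sublevel", "excluded"),
                        names_to = "indicator")
  ggplot2::ggplot(st, ggplot2::aes(.data$sublevel, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$policy)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded,
                                     colour = .data$policy), size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "policy sub-level", y = NULL, shape = "yield guard") +
    ggplot2::theme_minimal()
}

#' @method autoplot nfp_sweep
#' @export
autoplot.nfp_sweep <- function(object, ...) plot_sweep(object)

#' Plot cost-efficiency curves
#'
#' Policy cost against the achieved state leaching reduction, one curve per
#' policy; the canonical abatement-cost picture (cost rising steeply past
#' moderate reductions).
#'
#' @param curves one [cost_efficiency_curve()] tibble or several row-bound
#'   together.
#' @return a ggplot.
#' @export
plot_cost_efficiency <- function(curves) {
  d <- dplyr::filter(curves, .data$policy != "base")
  ggplot2::ggplot(d, ggplot2::aes(.data$reduction_pct, .data$policy_cost,
                                  colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "N leaching reduction (% of base)",
                  y = "policy cost (US$/ha)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the three field-level effects of a policy
#'
#' Scatter panels on field means across years: income vs base income,
#' leaching vs base leaching, and profit change vs base leaching, each with
#' its OLS line — the income, point-source-reduction and internalization
#' effects.
#'
#' @inheritParams field_effects
#' @return a ggplot.
#' @export
plot_field_effects <- function(outcomes, base_outcomes, plan,
                               policy_kind = "policy") {
  per_field <- function(x, cols) {
    x %>%
      dplyr::group_by(.data$region, .data$field_id) %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       .groups = "drop")
  }
  pol <- per_field(outcomes, c("profit_after", "leach2")) %>%
    dplyr::left_join(dplyr::select(plan, "region", "total_per_ha"),
                     by = "region")
  base <- per_field(base_outcomes, c("profit_after", "leach2")) %>%
    dplyr::rename(base_profit = "profit_after", base_leach2 = "leach2")
  d <- dplyr::inner_join(pol, base, by = c("region", "field_id"))
  panels <- dplyr::bind_rows(
    dplyr::transmute(d, panel = "income effect", x = .data$base_profit,
                     y = .data$profit_after + .data$total_per_ha),
    dplyr::transmute(d, panel = "point source reduction",
                     x = .data$base_leach2, y = .data$leach2),
    dplyr::transmute(d, panel = "internalization", x = .data$base_leach2,
                     y = .data$profit_after - .data$base_profit)
  )
  ggplot2::ggplot(panels, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "firebrick") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(title = policy_kind, x = "base-level value",
                  y = "policy value") +
    ggplot2::theme_minimal()
}

#' Plot the N balance vs N leaching diagnostic scenarios
#'
#' @param x an [n_balance_diagnostic()] result.
#' @return a ggplot faceted by scenario.
#' @export
plot_balance_diagnostic <- function(x) {
  pts <- attr(x, "points")
  labs <- x %>%
    dplyr::mutate(label = sprintf("s=%.2f%s r2=%.2f", .data$slope,
                                  .data$stars, .data$r_squared))
  ggplot2::ggplot(pts, ggplot2::aes(.data$n_balance, .data$leach2)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "firebrick") +
    ggplot2::facet_wrap(~scenario, scales = "free") +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = -Inf, y = Inf, label = .data$label),
                       hjust = -0.1, vjust = 1.5, size = 3,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "N balance (kg N/ha)",
                  y = "2-year N leaching (kg N/ha)") +
    ggplot2::theme_minimal()
}

#' @method autoplot nfp_balance_diag
#' @export
autoplot.nfp_balance_diag <- function(object, ...) {
  plot_balance_diagnostic(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
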