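policy_code <- function(kind) match(kind, policy_kinds) - 1L

#' Default sub-level sweep grids
#'
#' Price ratio 5 to 20 by 1 (kg maize/kg N), leaching fee 0 to 40 by 2
#' (US$/kg N), balance fee 0 to 4 by 0.25 (US$/kg N), voluntary reduction 0 to
#' 0.30 by 0.02.
#'
#' @param kind a policy kind other than `"base"`.
#' @return a numeric vector of sub-levels, starting at the base-equivalent.
#' @export
default_sublevels <- function(kind) {
  switch(match.arg(kind, policy_kinds[-1]),
    price_ratio = seq(5, 20, by = 1),
    leaching_fee = seq(0, 40, by = 2),
    balance_fee = seq(0, 4, by = 0.25),
    voluntary = seq(0, 0.30, by = 0.02)
  )
}

# evaluation-field covariates and curves for one held-out year
fold_eval_inputs <- function(dataset, held_out_year) {
  list(
    covs = dplyr::filter(dataset$covariates, .data$role == "evaluation",
                         .data$year == held_out_year),
    curves = dplyr::filter(dataset$curves, .data$role == "evaluation",
                           .data$year == held_out_year)
  )
}

#' Run the base-level (no-policy) pipeline
#'
#' For every weather year, trains the base recommender on all other years'
#' trial curves (stage 1-2) and applies it to the evaluation fields cropping
#' maize in the held-out year (stage 3). The per-fold recommenders are
#' returned for reuse by the voluntary policy and by diagnostics.
#'
#' @param dataset an [generate_dataset()] object.
#' @param prices market [prices()].
#' @param seed root seed for the recommender fits (independent substream per
#'   policy, sub-level and fold).
#' @param num_trees forest size.
#' @return a list of class `nfp_run`: `outcomes` (all folds stacked),
#'   `models` (per held-out year), `policy`, `prices`.
#' @export
run_base <- function(dataset, prices = nfertpolicy::prices(), seed = 1L,
                     num_trees = 300L) {
  run_policy(dataset, policy("base"), prices = prices, seed = seed,
             num_trees = num_trees)
}

#' Run the full three-stage pipeline for one policy sub-level
#'
#' Stage 1 gathers the trial response curves of every year but the held-out
#' one; stage 2 computes their policy-conditional EONRs and trains the
#' recommender; stage 3 recommends rates ex ante for the evaluation fields in
#' the held-out year and realizes outcomes on their curves. The voluntary
#' policy reuses the base-level recommenders (`base`), applying its reduction
#' at recommendation time.
#'
#' @inheritParams run_base
#' @param policy an [policy()] object (fee policies need thresholds attached).
#' @param base an `nfp_run` from [run_base()]; required for `"voluntary"`,
#'   optional reuse elsewhere is not meaningful since other policies retrain.
#' @return an `nfp_run` list (see [run_base()]).
#' @export
run_policy <- function(dataset, policy, prices = nfertpolicy::prices(),
                       base = NULL, seed = 1L, num_trees = 300L) {
  years <- dataset$weather$year
  reuse_base <- policy$kind == "voluntary"
  if (reuse_base && is.null(base)) {
    abort("the voluntary policy needs the base-level run (`base`)",
          class = "nfp_data_error")
  }
  sub_id <- if (is.na(policy$sublevel)) 0L else round(policy$sublevel * 1000)
  models <- list()
  outcomes <- purrr::map_dfr(seq_along(years), function(fold) {
    yr <- years[fold]
    model <- if (reuse_base) {
      base$models[[as.character(yr)]]
    } else {
      tt <- build_training_table(dataset, policy, held_out_year = yr,
                                 prices = prices)
      train_recommender(
        tt, num_trees = num_trees,
        seed = substream_seed(seed, policy_code(policy$kind), sub_id, fold))
    }
    models[[as.character(yr)]] <<- model
    ev <- fold_eval_inputs(dataset, yr)
    if (nrow(ev$covs) == 0) return(NULL)
    rates <- recommend(model, ev$covs, policy,
                       n_grid = dataset$config$n_grid)
    evaluate_fields(ev$curves, rates, policy, prices)
  })
  structure(list(outcomes = outcomes, models = models, policy = policy,
                 prices = prices), class = "nfp_run")
}

#' @export
print.nfp_run <- function(x, ...) {
  cat("<nfp_run>", x$policy$kind,
      if (!is.na(x$policy$sublevel)) paste("@", signif(x$policy$sublevel, 4)),
      ":", nrow(x$outcomes), "field-year outcomes\n")
  invisible(x)
}

#' Sweep a policy over its sub-level grid
#'
#' Re-runs the full pipeline at each sub-level (retraining the recommender per
#' sub-level and fold, except the voluntary policy which reuses the base
#' models), aggregates each run, applies the regional yield guard, and stacks
#' everything into a Table-style sweep summary. Fee policies receive the
#' regional thresholds derived from the base run unless overridden on
#' `thresholds`.
#'
#' @inheritParams run_policy
#' @param kind one of `"price_ratio"`, `"leaching_fee"`, `"balance_fee"`,
#'   `"voluntary"`.
#' @param sublevels sub-level grid; defaults to [default_sublevels()].
#' @param base the base-level [run_base()] result (required).
#' @param thresholds optional list(leach=, balance=) overriding
#'   [compute_thresholds()] on the base outcomes.
#' @return a list of class `nfp_sweep`: `summaries` (stacked
#'   [summarise_policy()] rows incl. the base row, with `excluded` flags),
#'   `outcomes` (list of per-sub-level outcome tables), `plans` (list of
#'   [compensate()] tables), `kind`, `thresholds`.
#' @export
run_sweep <- function(dataset, kind, base, sublevels = NULL,
                      prices = nfertpolicy::prices(), thresholds = NULL,
                      seed = 1L, num_trees = 300L) {
  kind <- match.arg(kind, policy_kinds[-1])
  sublevels <- sublevels %||% default_sublevels(kind)
  if (is.null(thresholds)) {
    thresholds <- compute_thresholds(base$outcomes)
  }
  base_summary <- summarise_policy(base$outcomes, base$outcomes,
                                   policy("base"))
  runs <- purrr::map(sublevels, function(s) {
    pol <- policy(kind, sublevel = s,
                  leach_thresholds = thresholds$leach,
                  balance_thresholds = thresholds$balance)
    run_policy(dataset, pol, prices = prices, base = base, seed = seed,
               num_trees = num_trees)
  })
  summaries <- purrr::map2_dfr(runs, sublevels, function(r, s) {
    summarise_policy(r$outcomes, base$outcomes, r$policy)
  })
  summaries <- yield_guard(dplyr::bind_rows(base_summary, summaries),
                           base_summary)
  plans <- purrr::map(runs, ~ compensate(.x$outcomes, base$outcomes,
                                         .x$policy))
  structure(list(
    summaries = summaries,
    outcomes = setNames(purrr::map(runs, "outcomes"), sublevels),
    plans = setNames(plans, sublevels),
    kind = kind, thresholds = thresholds, prices = prices
  ), class = "nfp_sweep")
}

#' @export
print.nfp_sweep <- function(x, ...) {
  cat("<nfp_sweep>", x$kind, "over", length(x$outcomes), "sub-levels\n")
  invisible(x)
}
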