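#' Build the training table for one leave-one-year-out fold
#'
#' One row per trial field x training year: the v5 covariates as predictors
#' and the policy-conditional EONR of that trial curve as the response. Rows
#' from the held-out year are excluded, so the fold's recommender never sees
#' the weather year it will be evaluated in. Under the maize-soybean rotation
#' the table has `(n_trial / 2) * (n_years - 1)` rows.
#'
#' @param dataset an [generate_dataset()] object (or any list with `curves`
#'   and `covariates` tibbles of the same shape).
#' @param policy an [policy()] object; the voluntary policy trains on
#'   base-level EONRs (its reduction is applied at recommendation time).
#' @param held_out_year the evaluation year excluded from training.
#' @param prices an [prices()] object.
#' @return a tibble: `field_id`, `year`, `eonr`, and the [v5_covariates()].
#' @export
build_training_table <- function(dataset, policy, held_out_year,
                                 prices = nfertpolicy::prices()) {
  if (!held_out_year %in% dataset$weather$year) {
    abort(sprintf("held_out_year %s is not a dataset year", held_out_year),
          class = "nfp_data_error")
  }
  trial <- dplyr::filter(dataset$curves, .data$role == "trial",
                         .data$year != held_out_year)
  eonr_policy <- if (policy$kind == "voluntary") {
    nfertpolicy::policy("base")
  } else {
    policy
  }
  targets <- eonr(trial, eonr_policy, prices)
  covs <- dplyr::filter(dataset$covariates, .data$role == "trial",
                        .data$year != held_out_year)
  dplyr::inner_join(targets, covs, by = c("field_id", "year")) %>%
    dplyr::select("field_id", "year", "eonr",
                  dplyr::all_of(v5_covariates()))
}

#' Train an N-rate recommender on a training table
#'
#' Fits the default tree-ensemble family (a 300-tree random forest via
#' \pkg{ranger}, single-threaded and seeded, hence deterministic) regressing
#' the policy-conditional EONR on the v5 covariates. Any regressor exposing
#' the `fit(table)` / `predict(covariates)` contract can be injected through
#' `family`.
#'
#' @param table an [build_training_table()] tibble (>= 10 rows).
#' @param seed integer seed for the forest.
#' @param num_trees number of trees.
#' @param family `"ranger"` or a function `(table, seed) -> object` with a
#'   `predict(object, newdata)` method returning continuous N rates.
#' @return an object of class `nfp_recommender`.
#' @export
train_recommender <- function(table, seed = 1L, num_trees = 300L,
                              family = "ranger") {
  if (nrow(table) < 10) {
    abort(sprintf("training table has %d rows; need at least 10",
                  nrow(table)),
          class = "nfp_data_error")
  }
  covs <- v5_covariates()
  miss <- setdiff(c("eonr", covs), names(table))
  if (length(miss) > 0) {
    abort(paste("training table is missing columns:", toString(miss)),
          class = "nfp_data_error")
  }
  fit <- if (is.function(family)) {
    family(table, seed)
  } else {
    ranger::ranger(
      dependent.variable.name = "eonr",
      data = as.data.frame(table[c("eonr", covs)]),
      num.trees = num_trees, seed = seed, num.threads = 1L
    )
  }
  structure(list(
    fit = fit,
    family = if (is.function(family)) "custom" else family,
    covariates = covs,
    n_train = nrow(table),
    seed = as.integer(seed)
  ), class = "nfp_recommender")
}

#' @export
print.nfp_recommender <- function(x, ...) {
  cat("<nfp_recommender>", x$family, "fit on", x$n_train, "trial curves\n")
  invisible(x)
}

# continuous prediction from either family
predict_continuous <- function(recommender, newdata) {
  covs <- recommender$covariates
  miss <- setdiff(covs, names(newdata))
  if (length(miss) > 0) {
    abort(paste("missing covariate(s):", toString(miss)),
          class = "nfp_data_error")
  }
  nd <- as.data.frame(newdata[covs])
  if (inherits(recommender$fit, "ranger")) {
    predict(recommender$fit, data = nd, num.threads = 1L)$predictions
  } else {
    as.numeric(predict(recommender$fit, newdata = nd))
  }
}

#' Ex-ante N rate recommendations for evaluation fields
#'
#' Predicts the policy-conditional EONR from v5 covariates, clips to the grid
#' range and snaps to the nearest grid point (ties toward the lower rate).
#' Under the voluntary policy the base-level prediction is scaled by
#' `(1 - sublevel)` and snapped down.
#'
#' @param recommender an [train_recommender()] object (for the voluntary
#'   policy: one trained at the base level).
#' @param newdata covariate tibble (one row per evaluation field-year).
#' @param policy the [policy()] being applied.
#' @param n_grid admissible N rates.
#' @return the input with an added `n_rate` column (kg N/ha, on the grid).
#' @export
recommend <- function(recommender, newdata, policy,
                      n_grid = seq(0, 320, by = 10)) {
  pred <- predict_continuous(recommender, newdata)
  rate <- if (policy$kind == "voluntary") {
    snap_to_grid((1 - policy$sublevel) * pred, n_grid, mode = "down")
  } else {
    snap_to_grid(pred, n_grid, mode = "nearest")
  }
  dplyr::mutate(newdata, n_rate = rate)
}
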