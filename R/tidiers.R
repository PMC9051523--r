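#' Tidy a fitted N-rate recommender
#'
#' One row per predictor with its impurity importance (when available from
#' the underlying forest).
#'
#' @param x an `nfp_recommender`.
#' @param ... unused.
#' @return a tibble with `term` and `importance`.
#' @method tidy nfp_recommender
#' @export
tidy.nfp_recommender <- function(x, ...) {
  imp <- if (inherits(x$fit, "ranger")) {
    v <- x$fit$variable.importance
    if (is.null(v)) setNames(rep(NA_real_, length(x$covariates)),
                             x$covariates) else v
  } else {
    setNames(rep(NA_real_, length(x$covariates)), x$covariates)
  }
  tibble::tibble(term = names(imp), importance = as.numeric(imp))
}

#' Glance at a fitted N-rate recommender
#'
#' @inheritParams tidy.nfp_recommender
#' @return a one-row tibble: out-of-bag `r.squared` and `mse` (when the
#'   underlying forest reports them), `num_trees`, `nobs`.
#' @method glance nfp_recommender
#' @export
glance.nfp_recommender <- function(x, ...) {
  if (inherits(x$fit, "ranger")) {
    tibble::tibble(r.squared = x$fit$r.squared,
                   mse = x$fit$prediction.error,
                   num_trees = x$fit$num.trees, nobs = x$n_train)
  } else {
    tibble::tibble(r.squared = NA_real_, mse = NA_real_,
                   num_trees = NA_integer_, nobs = x$n_train)
  }
}

#' Tidy a welfare report
#'
#' @param x an [welfare()] object.
#' @param ... unused.
#' @return a one-row tibble with the welfare components (US$/yr, kg/yr, %).
#' @method tidy nfp_welfare
#' @export
tidy.nfp_welfare <- function(x, ...) {
  tibble::as_tibble(x[c("load_reduction", "externality_reduction",
                        "policy_cost_total", "welfare_gain", "roi")])
}

#' Glance at a welfare report
#' @inheritParams tidy.nfp_welfare
#' @return a one-row tibble with the scaling assumptions and the ROI.
#' @method glance nfp_welfare
#' @export
glance.nfp_welfare <- function(x, ...) {
  tibble::as_tibble(x[c("externality_cost_per_kg", "state_area", "roi")])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
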