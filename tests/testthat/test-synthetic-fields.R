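test_that("site generation honours counts, roles, regions and determinism", {
  cfg <- synth_config(n_trial = 30, n_eval = 90, n_years = 4, seed = 5)
  sites <- generate_sites(cfg)
  expect_equal(nrow(sites), 120)
  expect_setequal(sites$role, c("trial", "evaluation"))
  expect_equal(sum(sites$role == "trial"), 30)
  # same regional proportions in both roles
  tab <- table(sites$region, sites$role)
  expect_equal(as.numeric(tab[, "trial"]) / 30,
               as.numeric(tab[, "evaluation"]) / 90)
  # soils physically valid
  expect_true(all(sites$sand + sites$clay <= 100))
  expect_true(all(sites$som > 0))
  # byte-identical regeneration under the same seed
  expect_identical(sites, generate_sites(cfg))

  # degenerate single-region population
  small <- generate_sites(synth_config(
    n_trial = 2, n_eval = 2, n_years = 2,
    region_props = c(south = 1, central = 0, north = 0),
    som_mean = c(south = 2, central = 3, north = 4)))
  expect_equal(nrow(small), 4)
  expect_true(all(small$region == "south"))
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(synth_config(n_trial = 7), "n_trial",
               class = "nfp_config_error")
  expect_error(synth_config(n_years = 1), "n_years",
               class = "nfp_config_error")
  expect_error(
    synth_config(region_props = c(south = 0.6, central = 0.6, north = -0.2)),
    "region_props", class = "nfp_config_error")
  expect_error(
    synth_config(som_mean = c(south = 4, central = 3, north = 2)),
    "som_mean", class = "nfp_config_error")
  expect_error(synth_config(n_grid = seq(10, 320, 10)), "n_grid",
               class = "nfp_config_error")
})

test_that("rotation halves drive curve and training-fold counts", {
  ds <- tiny_dataset()
  # every field-year curve tabulates the full 33-point grid
  counts <- dplyr::count(ds$curves, field_id, year)
  expect_true(all(counts$n == 33))
  # alternating maize years: each field appears in n_years / 2 seasons
  per_field <- dplyr::count(ds$covariates, field_id)
  expect_true(all(per_field$n == 3))
  # (n_trial / 2) x (n_years - 1) rows per leave-one-year-out fold
  tt <- build_training_table(ds, policy("base"),
                             held_out_year = ds$weather$year[2])
  expect_equal(nrow(tt), (8 / 2) * (6 - 1))
  # published scale: 120 fields x 29 weather years = 3,480 curves per fold
  pd <- full_trial_dataset()
  tt_full <- build_training_table(pd, policy("base"),
                                   held_out_year = pd$weather$year[1])
  tt_full <- tt_full[tt_full$field_id %in%
                         pd$sites$field_id[pd$sites$role == "trial"], ]
  expect_equal(nrow(tt_full), 3480)
})

test_that("response curves are concave-then-plateau in yield and strictly increasing in leaching", {
  ds <- tiny_dataset()
  chk <- ds$curves %>%
    dplyr::arrange(field_id, year, n_rate) %>%
    dplyr::group_by(field_id, year) %>%
    dplyr::summarise(
      leach_strict = all(diff(leach2) > 0),
      leach0_positive = leach2[1] > 0,
      yield_monotone = {
        i <- which.max(yield)
        all(diff(yield[seq_len(i)]) >= -1e-9)
      },
      plateau = all(abs(diff(yield[yield >= max(yield) - 1e-9])) < 1e-9),
      .groups = "drop")
  expect_true(all(chk$leach_strict))
  expect_true(all(chk$leach0_positive))
  expect_true(all(chk$yield_monotone))
})

test_that("limit cases: flat yield gives EONR 0; zero rate coefficient gives flat leaching", {
  flat <- tibble::tibble(field_id = 1L, year = 1L, region = "south",
                         role = "evaluation", n_rate = seq(0, 320, 10),
                         yield = 9000, leach2 = 10 + seq(0, 320, 10) * 0.01)
  expect_equal(eonr(flat, policy("base"))$eonr, 0)

  cfg0 <- synth_config(n_trial = 4, n_eval = 4, n_years = 4, seed = 3,
                       leach_rate_coef = 0, soy_carryover_frac = 0)
  ds0 <- generate_dataset(cfg0)
  spread <- ds0$curves %>%
    dplyr::group_by(field_id, year) %>%
    dplyr::summarise(rng = diff(range(leach2)), .groups = "drop")
  expect_true(all(spread$rng < 1e-9))
})

test_that("regional gradients match the south-to-north narrative", {
  ds <- gradient_dataset()
  base_rates <- eonr(ds$curves, policy("base"))
  oc <- evaluate_fields(ds$curves,
                        dplyr::mutate(base_rates, n_rate = eonr),
                        policy("base"))
  by_region <- oc %>%
    dplyr::group_by(region) %>%
    dplyr::summarise(eonr = mean(n_rate), leach = mean(leach2),
                     yield = mean(yield))
  g <- function(v) setNames(by_region[[v]], by_region$region)
  e <- g("eonr"); l <- g("leach"); y <- g("yield")
  expect_true(e[["south"]] > e[["central"]] && e[["central"]] > e[["north"]])
  expect_true(l[["south"]] < l[["central"]] && l[["central"]] < l[["north"]])
  expect_true(y[["south"]] < y[["central"]] && y[["central"]] < y[["north"]])
  # baseline (zero-N) leaching also rises northward
  l0 <- ds$curves %>%
    dplyr::filter(n_rate == 0) %>%
    dplyr::group_by(region) %>%
    dplyr::summarise(l = mean(leach2))
  l0 <- setNames(l0$l, l0$region)
  expect_true(l0[["south"]] < l0[["central"]] &&
                l0[["central"]] < l0[["north"]])
})

test_that("v5 covariates carry real signal about the base EONR", {
  ds <- test_pipeline()$ds
  hold <- ds$weather$year[5]
  tt <- build_training_table(ds, policy("base"), held_out_year = hold)
  rec <- train_recommender(tt, seed = 1)
  held_curves <- dplyr::filter(ds$curves, role == "trial", year == hold)
  truth <- eonr(held_curves, policy("base"))
  covs <- dplyr::filter(ds$covariates, role == "trial", year == hold)
  pred <- recommend(rec, covs, policy("base"))
  j <- dplyr::inner_join(truth,
                         dplyr::select(pred, field_id, year, n_rate),
                         by = c("field_id", "year"))
  rmse_rf <- sqrt(mean((j$eonr - j$n_rate)^2))
  rmse_const <- sqrt(mean((j$eonr - mean(tt$eonr))^2))
  expect_lt(rmse_rf, 0.8 * rmse_const)
})

test_that("the whole dataset is reproducible from the seed", {
  cfg <- synth_config(n_trial = 4, n_eval = 6, n_years = 4, seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$curves, d2$curves)
  expect_identical(d1$covariates, d2$covariates)
  # single-curve generator agrees with the dataset path
  site <- d1$sites[3, ]
  yr <- d1$covariates$year[d1$covariates$field_id == site$field_id][1]
  season <- d1$weather[d1$weather$year == yr, ]
  single <- generate_response_curve(site, season, cfg)
  from_ds <- dplyr::filter(d1$curves, field_id == site$field_id, year == yr)
  expect_equal(single$curve$yield, from_ds$yield)
  expect_equal(single$curve$leach2, from_ds$leach2)
})
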