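test_that("field outcomes decompose revenue, costs and fees correctly", {
  rates <- tibble::tibble(field_id = 1L, year = 1L, n_rate = 100)
  oc <- evaluate_fields(hand_curve(), rates, policy("base"))
  expect_equal(oc$gross_revenue, 0.158 * 9000)
  expect_equal(oc$fert_cost, 79)
  expect_equal(oc$profit_after, 1343)
  expect_equal(oc$fee_paid, 0)
  expect_equal(oc$collection, 0)
  expect_equal(oc$n_balance, 100 - 0.0115 * 9000)
  # off-grid recommendation is an error
  expect_error(
    evaluate_fields(hand_curve(),
                    tibble::tibble(field_id = 1L, year = 1L, n_rate = 57),
                    policy("base")),
    "grid", class = "nfp_data_error")
})

test_that("fees are linear in the exceedance and absent where not owed", {
  # leach2(100) = 20; threshold 18 -> exceedance 2 at 10 US$/kg
  p <- policy("leaching_fee", 10,
              leach_thresholds = c(south = 18, central = 18, north = 18))
  rates <- tibble::tibble(field_id = 1L, year = 1L, n_rate = 100)
  oc <- evaluate_fields(hand_curve(), rates, p)
  expect_equal(oc$fee_paid, 20)
  expect_equal(oc$profit_after, 1343 - 20)
  expect_equal(oc$collection, 20)
  # voluntary pays no fee; price-ratio pays the wedge as a collection
  expect_equal(evaluate_fields(hand_curve(), rates,
                               policy("voluntary", 0.1))$fee_paid, 0)
  pr <- evaluate_fields(hand_curve(), rates, policy("price_ratio", 10))
  expect_equal(pr$fee_paid, 0)
  expect_equal(pr$fert_cost, 10 * 0.158 * 100)
  expect_equal(pr$collection, (10 * 0.158 - 0.79) * 100)
})

test_that("collections average per region and conservation holds by region-year", {
  oc <- tibble::tibble(
    field_id = 1:4, year = 1L,
    region = c("south", "south", "north", "north"),
    collection = c(10, 30, 0, 8))
  gc <- government_collections(oc)
  s <- gc$by_region_year
  expect_equal(s$collections_per_ha[s$region == "south"], 20)
  expect_equal(s$collections_per_ha[s$region == "north"], 4)
  # paid-out component 1 equals collections received, region-year by
  # region-year, on a real fee run
  tp <- test_pipeline()
  run_oc <- tp$sweeps$leaching_fee$outcomes[["10"]]
  gc2 <- government_collections(run_oc)
  chk <- run_oc %>%
    dplyr::group_by(region, year) %>%
    dplyr::summarise(total = sum(collection), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::inner_join(gc2$by_region_year, by = c("region", "year"))
  expect_equal(chk$total, chk$collections_per_ha * chk$n_fields,
               tolerance = 1e-9)
})

test_that("compensation restores regional mean income to the base level", {
  tp <- test_pipeline()
  base_oc <- tp$base$outcomes
  # base against itself: both components vanish
  p0 <- compensate(base_oc, base_oc, policy("base"))
  expect_equal(p0$collections_per_ha, rep(0, 3))
  expect_equal(p0$policy_cost_per_ha, rep(0, 3), tolerance = 1e-9)
  # a binding fee run: income after compensation == base income, per region
  oc <- tp$sweeps$leaching_fee$outcomes[["10"]]
  plan <- tp$sweeps$leaching_fee$plans[["10"]]
  per_region <- function(x) {
    x %>%
      dplyr::group_by(region, field_id) %>%
      dplyr::summarise(p = mean(profit_after), .groups = "drop") %>%
      dplyr::group_by(region) %>%
      dplyr::summarise(p = mean(p))
  }
  inc <- per_region(oc) %>%
    dplyr::inner_join(plan, by = "region") %>%
    dplyr::mutate(income = p + total_per_ha)
  base_inc <- per_region(base_oc)
  expect_equal(inc$income, base_inc$p, tolerance = 1e-9)
  # voluntary policy: no collections, compensation is the policy cost alone
  vplan <- tp$sweeps$voluntary$plans[["0.12"]]
  expect_equal(vplan$collections_per_ha, rep(0, 3))
  expect_equal(vplan$total_per_ha, vplan$policy_cost_per_ha)
  expect_error(compensate(oc, NULL, policy("base")),
               class = "nfp_data_error")
})

test_that("aggregation weights years within fields, then fields equally", {
  oc <- tibble::tibble(
    field_id = c(1, 2, 2, 2), year = c(1, 1, 2, 3),
    region = "south",
    n_rate = c(100, 200, 200, 200),
    yield = c(8000, 12000, 12000, 18000),
    leach2 = c(10, 30, 30, 30),
    gross_revenue = 0, fert_cost = 0, fee_paid = 0,
    profit_after = c(100, 300, 300, 300),
    n_balance = 0, collection = 0)
  s <- summarise_policy(oc, policy = policy("base"))
  st <- dplyr::filter(s, scope == "state")
  # field 1 contributes 1/2 despite having 1 year vs field 2's 3 years
  expect_equal(st$profits, (100 + 300) / 2)
  expect_equal(st$yield_t_ha, (8 + 14) / 2)
  expect_equal(st$leach2, (10 + 30) / 2)
  # one field, one year: the summary is that outcome
  s1 <- summarise_policy(oc[1, ], policy = policy("base"))
  expect_equal(dplyr::filter(s1, scope == "state")$n_fert, 100)
})

test_that("abatement cost reproduces the policy-cost / avoided-leaching ratio", {
  tp <- test_pipeline()
  s <- tp$sweeps$voluntary$summaries
  base_leach <- s$leach2[s$policy == "base" & s$scope == "state"]
  row <- dplyr::filter(s, policy == "voluntary", sublevel == 0.1,
                       scope == "state")
  expect_equal(row$abatement_cost,
               row$policy_cost / (base_leach - row$leach2))
})

test_that("the yield guard flags only losses beyond 5%", {
  mk <- function(policy, sublevel, frac) {
    tibble::tibble(
      scope = c("region", "region", "region", "state"),
      region = c("south", "central", "north", "state"),
      policy = policy, sublevel = sublevel,
      yield_t_ha = c(12, 12.5, 13, 12.5) * frac,
      leach2 = 40, n_fert = 180, profits = 1800, gov_collections = 0,
      policy_cost = 0, abatement_cost = NA_real_, excluded = FALSE)
  }
  base <- mk("base", NA_real_, 1)
  flagged <- yield_guard(
    dplyr::bind_rows(base, mk("voluntary", 0.1, 0.96),
                     mk("voluntary", 0.2, 0.94),
                     mk("voluntary", 0.3, 0.95)),
    base)
  got <- dplyr::distinct(flagged, policy, sublevel, excluded)
  expect_false(got$excluded[is.na(got$sublevel)])            # base vs base
  expect_false(got$excluded[which(got$sublevel == 0.1)])     # 96%
  expect_true(got$excluded[which(got$sublevel == 0.2)])      # 94%
  expect_false(got$excluded[which(got$sublevel == 0.3)])     # exactly 95%
})
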