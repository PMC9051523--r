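test_that("price ratio arithmetic", {
  expect_equal(price_ratio(prices()), 5)
  expect_equal(price_ratio(prices(1, 1)), 1)
  # the N price that raises the ratio to the ~13 policy level
  expect_equal(price_ratio(prices(0.158, 2.0527)), 12.99, tolerance = 1e-3)
  expect_error(prices(0, 1), class = "nfp_domain_error")
  expect_error(prices(0.1, -1), class = "nfp_domain_error")
})

test_that("N balance is fertilizer minus grain removal", {
  expect_equal(n_balance(176, 12600), 31.1)
  expect_equal(n_balance(0, 0), 0)
  expect_equal(n_balance(100, 10000, grain_n_conc = 0), 100)
})

test_that("profit decomposition on a hand-built curve", {
  pr <- policy_profit(hand_curve(), policy("base"))
  expect_equal(pr$profit, c(790, 1343, 1343))
  # zero fee reproduces base profit at every rate
  thr <- fixed_thresholds()
  for (k in c("leaching_fee", "balance_fee")) {
    p0 <- policy(k, 0, leach_thresholds = thr$leach,
                 balance_thresholds = thr$balance)
    expect_equal(policy_profit(hand_curve(), p0)$profit, c(790, 1343, 1343))
  }
  # a threshold the curve never crosses leaves the fee at zero
  high <- policy("leaching_fee", 10,
                 leach_thresholds = c(south = 1e6, central = 1e6,
                                      north = 1e6))
  expect_equal(policy_profit(hand_curve(), high)$fee_paid, c(0, 0, 0))
  # binding fee is linear in the exceedance
  low <- policy("leaching_fee", 10,
                leach_thresholds = c(south = 15, central = 15, north = 15))
  expect_equal(policy_profit(hand_curve(), low)$fee_paid, c(0, 50, 250))
})

test_that("eonr maximises profit with ties broken toward the lowest rate", {
  # plateau: N = 100 and N = 200 give equal revenue gain net of cost? build
  # an explicit tie and check the lower rate wins
  tie <- tibble::tibble(field_id = 1L, year = 1L, region = "south",
                        role = "evaluation", n_rate = c(0, 100, 200),
                        yield = c(5000, 9000, 9500), leach2 = c(5, 10, 20))
  expect_equal(eonr(tie, policy("base"))$eonr, 100)
  # voluntary at zero reduction and ratio at the base ratio are identities
  curves <- dplyr::filter(curve_pool(), field_id %in% 1:20)
  base_e <- eonr(curves, policy("base"))
  expect_equal(eonr(curves, policy("voluntary", 0))$eonr, base_e$eonr)
  expect_equal(eonr(curves, policy("price_ratio", 5))$eonr, base_e$eonr)
  thr <- fixed_thresholds()
  expect_equal(
    eonr(curves, policy("leaching_fee", 0, leach_thresholds = thr$leach))$eonr,
    base_e$eonr)
  expect_equal(
    eonr(curves, policy("balance_fee", 0,
                        balance_thresholds = thr$balance))$eonr,
    base_e$eonr)
})

test_that("eonr equals the brute-force grid-search oracle on random curves", {
  curves <- curve_pool()
  n_curves <- nrow(dplyr::distinct(curves, field_id, year))
  expect_gte(n_curves, 200)
  thr <- fixed_thresholds()
  pols <- list(
    policy("base"),
    policy("price_ratio", 12),
    policy("price_ratio", 20),
    policy("leaching_fee", 7, leach_thresholds = thr$leach),
    policy("leaching_fee", 31, leach_thresholds = thr$leach),
    policy("balance_fee", 1.3, balance_thresholds = thr$balance),
    policy("balance_fee", 3.7, balance_thresholds = thr$balance),
    policy("voluntary", 0.17),
    policy("voluntary", 0.3)
  )
  for (p in pols) {
    got <- eonr(curves, p)
    want <- eonr_oracle(curves, p)
    expect_equal(
      dplyr::arrange(got, field_id, year)$eonr,
      dplyr::arrange(want, field_id, year)$eonr,
      info = paste(p$kind, p$sublevel))
  }
})

test_that("tightening any instrument never raises the optimal rate", {
  curves <- curve_pool()
  thr <- fixed_thresholds()
  grids <- list(
    price_ratio = c(5, 8, 12, 16, 20),
    leaching_fee = c(0, 5, 10, 20, 40),
    balance_fee = c(0, 1, 2, 3, 4),
    voluntary = c(0, 0.1, 0.2, 0.25, 0.3)
  )
  for (k in names(grids)) {
    rates <- sapply(grids[[k]], function(s) {
      p <- policy(k, s, leach_thresholds = thr$leach,
                  balance_thresholds = thr$balance)
      dplyr::arrange(eonr(curves, p), field_id, year)$eonr
    })
    expect_true(all(apply(rates, 1, function(r) all(diff(r) <= 0))),
                info = k)
  }
})

test_that("realized profit at the eonr dominates every other grid point", {
  curves <- dplyr::filter(curve_pool(), field_id %in% 1:30)
  thr <- fixed_thresholds()
  p <- policy("leaching_fee", 12, leach_thresholds = thr$leach)
  prof <- policy_profit(curves, p)
  best <- eonr(curves, p)
  chk <- prof %>%
    dplyr::group_by(field_id, year) %>%
    dplyr::summarise(max_profit = max(profit), .groups = "drop") %>%
    dplyr::inner_join(best, by = c("field_id", "year")) %>%
    dplyr::inner_join(dplyr::select(prof, field_id, year, n_rate, profit),
                      by = c("field_id", "year", "eonr" = "n_rate"))
  expect_true(all(chk$profit >= chk$max_profit - 1e-9))
})

test_that("fee thresholds reproduce the 60% / minus-60 rules", {
  mk <- function(region, leach, balance) {
    tibble::tibble(region = region, field_id = seq_along(leach),
                   year = 1L, leach2 = leach, n_balance = balance)
  }
  oc <- dplyr::bind_rows(
    mk("south", c(20, 40), c(61, 81)),    # means 30 and 71
    mk("central", c(0, 0), c(10, 10)),
    mk("north", c(10, 10), c(0, 0))
  )
  thr <- compute_thresholds(oc)
  expect_equal(thr$leach[["south"]], 18)       # 0.6 x 30
  expect_equal(thr$balance[["south"]], 11)     # 71 - 60
  expect_equal(thr$leach[["central"]], 0)
  expect_error(compute_thresholds(mk("south", 1, 1)), "region",
               class = "nfp_data_error")
})

test_that("policy constructor enforces sub-level ranges and thresholds", {
  expect_error(policy("price_ratio", 4), class = "nfp_config_error")
  expect_error(policy("leaching_fee", 41,
                      leach_thresholds = fixed_thresholds()$leach),
               class = "nfp_config_error")
  expect_error(policy("voluntary", 0.5), class = "nfp_config_error")
  expect_error(policy("leaching_fee", 10), class = "nfp_config_error")
  expect_error(policy("balance_fee", 1, balance_thresholds = c(south = 1)),
               class = "nfp_config_error")
  expect_silent(policy("voluntary", 0.2))
})
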