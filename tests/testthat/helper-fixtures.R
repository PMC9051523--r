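# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) {
    assign(key, force(expr), .fixture_env)
  }
  get(key, .fixture_env)
}

# small dataset for structural / property checks (8 + 24 fields, 6 years)
tiny_dataset <- function() {
  memo("tiny", generate_dataset(
    synth_config(n_trial = 8, n_eval = 24, n_years = 6, seed = 101)))
}

# wider population for Monte-Carlo gradient checks (>= 500 fields)
gradient_dataset <- function() {
  memo("gradient", generate_dataset(
    synth_config(n_trial = 24, n_eval = 500, n_years = 6, seed = 42)))
}

# pool of random response curves for oracle / monotonicity properties
curve_pool <- function() {
  memo("pool", {
    ds <- generate_dataset(
      synth_config(n_trial = 8, n_eval = 100, n_years = 6, seed = 77))
    ds$curves
  })
}

# trial fields at the full published scale (fold arithmetic only)
full_trial_dataset <- function() {
  memo("full_trial", generate_dataset(
    synth_config(n_trial = 240, n_eval = 2, n_years = 30, seed = 11)))
}

# full test-preset pipeline: base run, thresholds, all four sweeps on the
# default sub-level grids; shared by the acceptance suite
test_pipeline <- function() {
  memo("pipeline", {
    ds <- generate_dataset(synth_config(preset = "test", seed = 202))
    base <- run_base(ds, seed = 202)
    thresholds <- compute_thresholds(base$outcomes)
    sweeps <- lapply(
      setNames(nm = c("price_ratio", "leaching_fee", "balance_fee",
                      "voluntary")),
      function(k) run_sweep(ds, k, base, thresholds = thresholds, seed = 202))
    list(ds = ds, base = base, thresholds = thresholds, sweeps = sweeps)
  })
}

# hand-checkable 3-point response curve: Y = 5000/9000/9500 at N = 0/100/200
hand_curve <- function() {
  tibble::tibble(
    field_id = 1L, year = 1L, region = "south", role = "evaluation",
    n_rate = c(0, 100, 200),
    yield = c(5000, 9000, 9500),
    leach2 = c(10, 20, 40)
  )
}

# independent brute-force EONR oracle: plain loops and arithmetic, no reuse
# of the package's profit path
eonr_oracle <- function(curves, policy, prices = nfertpolicy::prices()) {
  key <- unique(curves[c("field_id", "year")])
  out <- numeric(nrow(key))
  for (i in seq_len(nrow(key))) {
    cu <- curves[curves$field_id == key$field_id[i] &
                   curves$year == key$year[i], ]
    cu <- cu[order(cu$n_rate), ]
    p_n <- if (policy$kind == "price_ratio") {
      policy$sublevel * prices$p_maize
    } else {
      prices$p_n
    }
    prof <- prices$p_maize * cu$yield - p_n * cu$n_rate
    if (policy$kind == "leaching_fee") {
      thr <- policy$leach_thresholds[[cu$region[1]]]
      prof <- prof - policy$sublevel * pmax(0, cu$leach2 - thr)
    }
    if (policy$kind == "balance_fee") {
      thr <- policy$balance_thresholds[[cu$region[1]]]
      bal <- cu$n_rate - policy$grain_n_conc * cu$yield
      prof <- prof - policy$sublevel * pmax(0, bal - thr)
    }
    best <- cu$n_rate[prof == max(prof)]
    best <- min(best)
    if (policy$kind == "voluntary") {
      base_prof <- prices$p_maize * cu$yield - prices$p_n * cu$n_rate
      b <- min(cu$n_rate[base_prof == max(base_prof)])
      target <- (1 - policy$sublevel) * b
      best <- max(cu$n_rate[cu$n_rate <= target], min(cu$n_rate))
    }
    out[i] <- best
  }
  tibble::tibble(field_id = key$field_id, year = key$year, eonr = out)
}

# fixed thresholds usable with any synthetic dataset in tests
fixed_thresholds <- function() {
  list(
    leach = c(south = 18, central = 23, north = 29),
    balance = c(south = 11, central = -23, north = -55)
  )
}

benchmark_indicators <- function() {
  readr::read_csv(
    system.file("extdata", "illinois_benchmark_indicators.csv",
                package = "nfertpolicy"),
    show_col_types = FALSE, na = "NA")
}

benchmark_scaling <- function() {
  readr::read_csv(
    system.file("extdata", "illinois_benchmark_scaling.csv",
                package = "nfertpolicy"),
    show_col_types = FALSE)
}
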