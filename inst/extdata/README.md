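# Bundled reference tables

- `illinois_benchmark_indicators.csv` — the published regional/state indicator
  benchmark for the Illinois maize N-policy assessment this package models:
  base-level situation and the four policy instruments at the sub-levels that
  achieve a 20% state-wise N leaching reduction. Units: yield t/ha, leaching
  and fertilizer N kg/ha, money US$/ha, abatement cost US$/(kg ha). Sub-level
  units: price ratio kg maize/kg N, fees US$/kg, voluntary reduction %.
- `illinois_benchmark_scaling.csv` — the published state-scale welfare
  constants used to scale per-hectare results.

These are printed reference values used by tests and `scripts/acceptance.R` to
recompute derived arithmetic (reductions, abatement costs, welfare, ROI); the
simulation pipeline itself never reads them.
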