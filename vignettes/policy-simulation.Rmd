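---
title: "Methods: simulating N-fertilizer policy instruments on synthetic field populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating N-fertilizer policy instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `nfertpolicy`: what is simulated and
why, the assumptions baked into each stage, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic data can and
cannot tell you about real field populations.

## 1. The decision problem

A risk-neutral farmer choosing a fertilizer N rate for maize solves

$$\mathrm{EONR} = \arg\max_{N \in \mathcal{G}} \; p_m Y(N) - p_N' N - \mathrm{fee}(N),$$

on the discrete grid $\mathcal{G} = \{0, 10, \dots, 320\}$ kg N/ha. The four
policy instruments enter in exactly one place each:

* **price ratio** (target ratio $r \in [5, 20]$ kg maize/kg N): the effective
  N price becomes $p_N' = r\,p_m$, maize price unchanged — a tax on N;
* **leaching fee** ($f \in [0, 40]$ US\$/kg): $\mathrm{fee}(N) = f \max(0,
  L(N) - T^{\mathrm{leach}}_{\mathrm{region}})$, charged on the 2-year
  leaching of the maize-year curve (maize year plus the following soybean
  year);
* **balance fee** ($f \in [0, 4]$ US\$/kg): same form on the surplus
  indicator $NB(N) = N - c_g Y(N)$ with grain N concentration
  $c_g = 0.0115$ kg N/kg grain (maize-year fertilizer and removal only);
* **voluntary reduction** ($v \in [0, 0.30]$): no fee; the base-level
  recommendation is scaled by $1 - v$ and snapped *down* to the grid.

Base prices are $p_m = 0.158$ and $p_N = 0.79$ US\$/kg — price ratio 5.
Profit ties at the optimum are broken toward the **lowest** N rate; the
convention is environmentally conservative and makes the discrete argmax
deterministic.

Fee thresholds are regional by construction: baseline leaching is dominated
by soil-organic-matter mineralization, which rises from south to north, so a
uniform threshold would concentrate the burden on one end of the gradient.
`compute_thresholds()` sets the leaching threshold to 60% of the mean
base-level leaching of each region and the balance threshold to the mean
base-level balance minus 60 kg/ha, both computed with the standard
aggregation rule (equal year weights within a field, then equal field
weights).

## 2. The three-stage pipeline

For every weather year $t$ (leave-one-year-out):

1. **Trial data.** All trial-field response curves from years $\ne t$. Under
   the alternating maize–soybean rotation each fold has
   $(n_{\mathrm{trial}}/2)(n_{\mathrm{years}}-1)$ curves; `n_trial` must be
   even so the two rotation halves are equal.
2. **Recommendation tool.** The policy-conditional EONR of each trial curve
   is the response; the predictors are early-season (v5) covariates only —
   surface residue, soil mineral N 0–60 cm, extractable soil water, water
   holding capacity, soil organic matter, sand, clay, rain/temperature/
   radiation to v5, long-term yield, LAI at v5. The default learner is a
   300-tree random forest (`ranger`, single-threaded, seeded — hence
   deterministic); one forest is trained per (policy, sub-level, fold). Any
   regressor with a fit/predict contract can be injected. A policy never
   changes the *information* available, only the profit function, so policy
   effects are comparable across learners.
3. **Evaluation.** The fold's forest recommends rates ex ante for the
   evaluation fields cropping maize in year $t$ (predictions clipped to
   [0, 320] and snapped to the nearest grid point, ties down); yield and
   leaching are read off those fields' curves, and the economic decomposition
   (revenue, fertilizer cost incl. any tax, fee, profit, collection) is
   recorded per field-year. Every field represents 1 ha, so per-ha and
   per-field means coincide.

The voluntary policy deliberately reuses the *base-level* forests and scales
their recommendations by $1-v$ at recommendation time — training on reduced
targets *and* reducing predictions would apply the reduction twice.

**Compensation.** Collections are returned per region as an equal per-hectare
lump sum (component 1); a second component covers the *policy cost* — the
drop in regional mean profit that remains after collections are returned,
i.e. the deadweight loss. By construction the plan restores regional mean
income exactly; being lump-sum, it cannot re-enter an individual field's
first-order condition. Policy cost is defined on regional means, not per
field. The price-ratio instrument's collection is the tax wedge
$(p_N' - p_N)N$ only: the base fertilizer cost is a market transaction, not
a transfer to the regulator.

**Yield guard.** Sub-levels whose regional yield falls below 95% of base in
any region are flagged and excluded from cost-efficiency curves — beyond
that, supply shocks would move output prices, which the model holds fixed.
The boundary is strict: exactly 95% is kept.

## 3. The synthetic field population

The generator stands in for a process-based crop-model dataset that is not
redistributable. It reproduces the statistical structure the analysis
depends on, not the physiology.

**Sites.** Fields are split into three regions (default equal proportions;
assignment is by proportion, not geography) and into trial/evaluation roles
with identical regional proportions. Regional gradients, south to north:
soil organic matter (SOM) means 1.8 / 3.0 / 4.2%, attainable yield means
12,600 / 13,100 / 13,800 kg/ha. Texture is uniform within broad bounds;
water holding capacity is a linear function of SOM and texture plus noise.

**Weather.** One shared year effect (the blocking factor for
leave-one-year-out): log-normal spring rain (median 300 mm), Gaussian
thermal time (950 ± 80 °C d) and radiation (1150 ± 90 MJ/m²). Three latent
multipliers derive from the same draws — season quality (on attainable
yield), mineralization factor (on soil N supply), leaching season (on
baseline leaching) — which is what makes the observable weather covariates
informative.

**Yield curves.** For each field-year, yield is quadratic in *total*
plant-available N ($N$ + soil supply $N_s$), plateauing at the attainable
yield when total N reaches a vertex $N_v \sim 250 \pm 12$ kg/ha:

$$Y(N) = Y_{att}\left[1 - \left(1 - \tfrac{\min(N + N_s,\, N_v)}{N_v}\right)^{2}\right].$$

Algebraically this is the quadratic-plateau family
$\min(Y_{max},\, Y_0 + sN - qN^2)$ with field-year-specific coefficients.
Soil N supply $N_s = 18 \cdot \mathrm{SOM} \cdot m_t \cdot \varepsilon$
(kg N per % SOM, season mineralization factor $m_t$, log-normal noise) is
the mechanism that makes the EONR *fall* northward while yield rises: richer
soils need less fertilizer. Attainable yield carries 13% log-normal
field-year noise — deliberately generous, so that yield (and hence the
N-balance indicator) varies substantially for reasons unrelated to leaching
(see §5).

**Leaching curves.** Two-year leaching is

$$L(N) = L_{base} + c_f\,k\,\mathrm{softplus}\!\left(\tfrac{N - N_d}{k}\right) + 0.3\,\mathrm{cummax}\,\max(0,\, N - c_g Y(N)),$$

* $L_{base} = 8 \cdot \mathrm{SOM} \cdot w_t \cdot \varepsilon$: baseline
  (zero-N) leaching from mineralization, positive everywhere, rising with
  SOM and wet springs ($w_t$); 25% log-normal field noise.
* The softplus term is rate-driven leaching that accelerates once fertilizer
  approaches crop demand ($N_d = N_v - N_s - 60$; softness $k = 25$ kg/ha).
  Its slope limit is $c_f = 0.25 \cdot (\mathrm{SOM}/3)^{1.5}$ kg leached per
  kg N: high-mineralization soils lose a larger share of marginal fertilizer
  N. This exponent is what concentrates rate-driven leaching — and therefore
  policy-induced reductions — on high-leaching fields (the point-source
  reduction effect, regression slope of policy vs base leaching below 1). With
  a uniform slope the surplus carryover term dominates and reductions
  concentrate on *low*-leaching southern fields instead.
* The third term is the soybean-year carryover: a fixed 0.3 fraction of the
  maize-year N surplus. The source data report only the 2-year total, so the
  partition is a design choice exposed as `soy_carryover_frac`.

**Covariates.** Soil mineral N at v5 is a noisy observation of $N_s$
(the main predictable driver of the EONR); LAI at v5 tracks attainable
yield; extractable soil water couples WHC and spring rain; the site and
weather variables enter directly. On default data the forest's out-of-fold
RMSE beats the constant-mean predictor by well over 20% (asserted in the
test suite), so the recommendation stage is exercised meaningfully.

**Calibration.** The defaults were set, once, to reproduce the qualitative
conditions the analysis assumes: regional means of EONR ≈ 200/180/160 kg/ha
falling northward against rising yield and leaching; all four instruments
able to reach a 20% state leaching reduction inside their sub-level ranges
with regional yield losses under ~5% near the target; and the N-balance
diagnostic of §5. They are config parameters, not constants, and the test
suite re-verifies the properties rather than the numbers.

## 4. Numerical conventions

* **Grid snapping**: nearest grid point with exact midpoints going down;
  the voluntary reduction always snaps down. Predictions are clipped to
  [0, 320] before snapping.
* **Monotone leaching**: the surplus term $\max(0, N - c_g Y(N))$ can dip
  locally where the yield slope exceeds $1/c_g$; a running maximum over the
  grid keeps the carryover non-decreasing, and the strictly increasing
  softplus term makes total leaching strictly increasing.
* **Clamping**: SOM below 0.4%, WHC outside [80, 400] mm, vertex outside
  [150, 350] kg/ha and long-term yield below 6,000 kg/ha are clamped;
  draws this extreme are vanishingly rare at the default variances.
* **Seeding**: one root seed; per-field, per-year and per-(policy,
  sub-level, fold) child streams are derived by a Lehmer-style counter fold
  (`substream_seed()`), so changing one count does not reshuffle unrelated
  draws and every fit is reproducible. All seeds stay below $2^{31}$.
* **Degenerate inputs**: an empty region fails threshold computation; a
  diagnostic scenario without indicator variance returns missing values with
  a warning; off-grid rates and missing covariates raise typed errors
  (`nfp_config_error`, `nfp_data_error`, `nfp_domain_error`).
* **Reporting**: indicators are kept at full precision internally; rounding
  (yield to 0.1 t/ha, money to whole US\$/ha) is left to the caller or the
  reporting layer.
* **Abatement cost** is policy cost per kg of leaching avoided; when a
  sub-level avoids nothing the value is reported missing rather than
  infinite.
* **Arc elasticity** uses the midpoint convention
  $|\Delta Q / \bar Q| / |\Delta P / \bar P|$ on two adjacent price-ratio
  sub-levels.

## 5. The N-balance diagnostic

`n_balance_diagnostic()` regresses 2-year leaching on the N balance across
five dataset designs: (A) one location × four fixed rates, (B) 45 locations
× four rates, (C) many locations at one common rate, (D) 45 and (E) up to
5,000 locations at recommended base rates (sizes shrink automatically on
small datasets; locations are seeded samples of field-years). Within a
location the two quantities move together — both increase with N — so A and
B show strong positive slopes. Across locations at a common rate the
balance is driven by yield while leaching is driven by mineralization; in
the generator the high-SOM fields have both higher yield (lower balance)
and higher leaching, while the surplus carryover couples them positively,
and the generous rate-independent yield noise dilutes what remains. The
resulting scenario-C $r^2$ stays below 0.02 at default scale — the stated
property of the source data that makes a balance fee a poor proxy for a
leaching fee. This is a *designed* property of the generator, verified by
the acceptance suite, not an emergent discovery about real fields.

## 6. Problem sizes and runtime

The default `test` preset — 24 trial + 120 evaluation fields over 10 years,
full default sub-level grids (16 ratio, 21 leaching-fee, 17 balance-fee, 16
voluntary levels) — was chosen so that a complete four-instrument study
(base run, four sweeps with per-sub-level forest refits, effects and
diagnostics) completes in about a minute on one CPU, while keeping enough
fields per region (40) for stable regional means. The `full` preset
(240 + 4,030 fields, 30 years) reproduces the published study's dimensions —
3,480 trial curves per fold — and runs the same code unchanged in tens of
minutes. Tests and the acceptance script use the test preset; the
published-scale generator is exercised only for fold bookkeeping.

## 7. Design decisions on open questions

* The exact after-fee profit equations of the source study's supplementary
  material are not public; the forms in §1 are reconstructed from the policy
  definitions and are the package's definition of record. Fees are charged
  once per rotation cycle on the 2-year leaching total, undiscounted.
* Farm profits cover the maize year only; leaching covers both years. Mixing
  the two horizons is intentional: the fee is levied on the full
  environmental footprint of the maize-year N decision.
* The recommender is retrained per (policy, sub-level, fold) but the fitted
  forests are reused in memory within a run (the voluntary policy reuses the
  base forests); a disk cache was considered and dropped — deterministic
  seeding makes recomputation bit-identical, and state on disk would be a
  second source of truth.
* Run configs are YAML: human-editable, nested, round-trips losslessly with
  `yaml`, and unknown keys are rejected rather than ignored.
* Regions are sampling strata, not geography; no spatial autocorrelation is
  modelled, so "interleaving" trial and evaluation fields reduces to equal
  regional proportions.

## 8. Limitations

The generator emulates marginal structure, not mechanism: no daily water or
N dynamics, no within-season weather interaction with the response shape
beyond scalar multipliers, no spatial correlation, no manure N, no
management practices other than the N rate, and a single curve family.
Passing tests therefore demonstrate that the *pipeline* behaves correctly
under the assumed structure — monotone policy pressure, conservation of
transfers, income restoration, the designed field-level effects — not that a
particular fee level would achieve a particular reduction in any real
region. Behavioral responses (risk aversion, partial adoption), land-use
change, administrative costs and price feedbacks are all outside scope, as
are joint or stacked instruments and non-regional thresholds.
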