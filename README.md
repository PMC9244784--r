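# wheatsynth

Synthesis tools for water and nitrogen management effects on wheat
production across China's four wheat regions (Center, East, North,
Northwest). Starting from a flat table of paired treatment/control field
observations (irrigated/fertilized vs. unirrigated/unfertilized), the
package estimates how water and N input change grain yield, water
productivity (WP, kg m⁻³) and fertilizer N use efficiency (NUE, kg kg⁻¹),
locates region-wise optimal input levels, quantifies water/N saving
potentials, attributes the responses to climate, soil and management
drivers, and values the savings environmentally and economically.

It is written for agronomists and quantitative ecologists doing
literature synthesis: the same pipeline runs on a real extraction table
(CSV) or on the package's literature-shaped synthetic generator, which
has known ground truth and is how every estimator here is validated.

## The statistics at the core

* **Effect sizes** — log response ratios `RR = ln(X_t / X_c)` per pair;
  `(e^RR − 1)·100` is the percent change. Pairs are weighted by
  `n_t·n_c/(n_t + n_c)` replicates (unit weights when replicates are
  unreported).
* **Pooling** — the random-effects model
  `RR_ij = μ + u_i + e_ij`, `u_i ~ N(0, τ²)` (study), `e_ij ~ N(0, σ²/w_ij)`,
  fitted by REML with σ² profiled out in closed form; 95% CIs by
  cluster bootstrap (studies resampled with replacement, 4,999
  iterations, bias-corrected percentile).
* **Optima and saving potential** — the optimal input is the center of
  the lowest input bin attaining maximal mean yield; above-optimal
  observations save `input − opt` (mm or kg ha⁻¹) and
  `(input − opt)/max·100` (%); W⁺/W⁻ and N⁺/N⁻ strata follow.
* **Attribution** — recursive path models (standardized equation-wise
  OLS, exact ML for this model class) with χ² model fit, and CART
  regression trees ranked by risk change per branch node under 10-fold
  cross-validation.
* **Valuation** — inventory × characterization-factor LCA over 8 impact
  categories (GWP, PED, AP, ADP, EP, RI, POFP, ETx) per hectare and per
  tonne, and yuan-denominated water/N/carbon saving values per hectare
  and per region.

## Worked example

The numbered drivers under `analysis/` run the whole study on a
synthetic dataset (seed via `WS_SEED`, default 1) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_meta_analysis.R
```

```
Generated 985 paired observations from 126 studies (seed 1).
ET available for 43% of pairs; NUE pairs: 96.
Overall yield response: RR = 0.402 (95% CI 0.366 to 0.438), i.e. +49%
vs unirrigated/unfertilized controls (985 pairs, 126 studies).
Overall wp response: +23% (n = 424).
```

The pooled RR of 0.402 means irrigation plus fertilization raised yields
by 49% on this draw (the generator's truth is a hump-shaped response
with study effects of SD 0.2, so the estimate and its CI are checked
against known parameters). Continuing:

```sh
Rscript analysis/03_optima_saving.R   # optima, saving potentials, level regressions
Rscript analysis/04_path_model.R      # stratified path models
Rscript analysis/05_cart.R            # tree ranking + 10-fold CV
Rscript analysis/06_lca.R             # impact characterization
Rscript analysis/07_economics.R       # valuation
```

`07` prints, for the published regional inputs, rows such as

```
region  kind  saving_phys value_input value_carbon  total carbon_share_pct region_total
Northwest water        76      349.60         0.88 350.48             0.25    513150035
```

i.e. 76 mm of saved water in the Northwest is worth 349.60 yuan ha⁻¹ at
the regional irrigation price, plus 0.88 yuan ha⁻¹ of avoided emissions
at the regional carbon price, 350.48 yuan ha⁻¹ in total — about 0.51
billion yuan across the region's 1.46 M irrigated hectares.

The same machinery is available directly:

```r
library(wheatsynth)
g <- generate_dataset(generator_config(seed = 1))
eff <- compute_rr(g$dataset, "yield")
fit_reml(eff)                      # pooled RR, tau2, percent change
bootstrap_ci(eff, n_iter = 4999, seed = 1)
opt <- find_optima_all(g$dataset)
saving_potential(g$dataset, opt, "water")
```

## Repository layout

```
R/                  package code (all computation lives here)
analysis/01..07_*.R numbered narrative drivers over the package
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  headline-quantity recomputation (JSON out)
vignettes/          methods vignette (models, assumptions, choices)
inst/extdata/       synthetic LCA factor/coefficient fixtures (CSV)
```
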