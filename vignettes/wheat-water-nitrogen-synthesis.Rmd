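---
title: "Synthesizing water and nitrogen management effects on wheat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing water and nitrogen management effects on wheat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(wheatsynth)
```

## The problem

Across China's four wheat production regions (Center, East, North,
Northwest — 25 provinces in total), field studies compare irrigated and/or
N-fertilized treatments against unirrigated, unfertilized controls. Each
study contributes one or more paired observations: treatment and control
grain yield, total water input (precipitation plus irrigation), N
fertilizer rate, and — where reported — evapotranspiration, directly
extracted water productivity (WP, kg grain per m^3 of evapotranspired
water) and fertilizer N use efficiency (NUE, kg grain per kg N). The
package synthesizes such a table of paired observations into:

1. pooled effect sizes of water/N input on yield, WP and NUE, overall and
   by region and input level;
2. region-wise optimal input levels and the water/N *saving potential* of
   above-optimal observations;
3. attribution of the responses to climate, soil and management drivers
   (path analysis and regression-tree importance ranking);
4. life-cycle impact characterization of the regional input intensities;
5. monetary valuation of input savings and avoided greenhouse-gas
   emissions.

`analysis/01...07` are thin numbered drivers over the package functions;
everything they do is callable (and tested) directly.

## Effect sizes and pooling

The effect-size metric is the log response ratio
`rr = ln(treatment) − ln(control)`; `(exp(rr) − 1)·100` is the percent
change. WP ratios fall back to `y/(10·ET)` when WP was not directly
extracted (the factor 10 is dimensional: 1 mm of water over 1 ha is
10 m^3). NUE ratios require directly extracted values, because an
unfertilized control has no defined yield-per-kg-N; pairs that cannot be
computed are excluded with an explicit reason, never silently.

Per-observation sampling variances are unavailable in literature
extraction (means are reported without SDs), so observations are weighted
by the replicate rule `w = rep_t·rep_c/(rep_t + rep_c)`, the standard
replicate-based weighting in agronomic meta-analysis, with `w = 1` when
replicate counts are missing. Pooling uses the hierarchical model

    rr_ij = mu + u_i + e_ij,   u_i ~ N(0, tau2),  e_ij ~ N(0, sigma2 / w_ij)

with study `i` as the random effect, fitted by REML. Writing
`lambda = tau2/sigma2`, per-study sufficient statistics reduce the
restricted likelihood to a closed form in which `sigma2` profiles out
analytically (`sigma2_hat = R(lambda)/(N−1)`); the remaining
one-dimensional criterion is minimized by safeguarded bisection on its
derivative (60 halvings on `lambda in [0, 1e6]`, i.e. resolution far below
any statistical noise), with `tau2 >= 0` by construction. A single study,
or zero dispersion, collapses to `tau2 = 0` exactly. The implementation is
validated against (a) a naive grid-search maximizer of the textbook
restricted likelihood built from full covariance matrices, to 1e-4 on
`tau2`, and (b) `lme4::lmer(rr ~ 1 + (1|study), weights = w)`, which fits
the identical model, to machine precision. `tau2_fixed = 0` gives the
fixed-effect (inverse-variance weighted mean) solution.

Confidence intervals use a cluster bootstrap: studies are resampled with
replacement (observations stay with their study, respecting within-study
dependence), the model is refitted on each resample, and a bias-corrected
(BC) percentile interval is taken. BC rather than BCa: the acceleration
constant would require a jackknife that adds little at these cluster
counts. The refits are vectorized across all resamples (the per-study
statistics are matrix-indexed and the bisection runs on vectors), so
4,999 iterations on a hundred studies take well under a second.
Observation-level resampling is available behind `cluster = FALSE`.
Degenerate cases (all effects identical; all resamples equal) return a
point interval, and a degenerate bias correction falls back to the plain
percentile interval with a warning.

Subgroup summaries (`overall`, `region`, `water_level`, `n_level`) refuse
to estimate subgroups with fewer than 3 effects (configurable) and mark
them not-estimable instead.

## Optima, classification and saving potentials

"The minimal input producing maximal yield" must be operationalized over
scattered observations: treated observations are binned by input level
(default 50 mm water, 30 kg/ha N, equal width), and the optimum is the
center of the lowest-input bin whose mean treatment yield attains the
maximum over bins, ties broken toward lower input. Observations exactly at
the optimum are classed below (`W_minus`/`N_minus`): the optimum itself is
never counted as overuse, which also makes the minimum saving 0 whenever
any at-or-below-optimal observation exists. Above-optimal observations
save `input − optimum` absolutely and `(input − optimum)/max·100` percent,
where `max` is the regional maximum input; relative savings are averaged
per observation, never as a ratio of means. Within-level input-response
regressions are OLS of the outcome on `input/1000` (water in metres, N in
t/ha — the scaling that puts slopes on the order of units); insignificant
cells are flagged, not suppressed, and zero-variance regressors yield an
explicit undefined flag.

A caveat that the validation makes explicit: binned-mean optimum finding
is only reliable when the *other* input's mix within a bin does not swamp
the between-bin signal. Near the optimum the yield surface is flat, so on
data where N varies freely the water-bin argmax can wander by a bin even
without noise. The recovery checks therefore pin the other input at its
optimum, isolating the response being estimated; on real (noisy,
confounded) data the estimated optima should be read as bin-resolution
quantities.

## Path analysis

The driver model is a recursive system of observed variables: climate
(MAT), initial soil nutrients (SOC, AK, AP) and management (water, N) act
on the yield response; the yield response feeds the WP response, and both
feed the NUE response. For a recursive model with uncorrelated errors,
maximum likelihood is exactly equation-wise OLS on standardized variables,
so each endogenous variable's coefficients are its standardized multiple
regression on its parents; no iterative SEM optimizer is needed. The
implied correlation matrix is assembled as
`(I−B)^{-1} Psi (I−B)^{-T}` and compared with the observed one through
`chi_square = (n−1)·F_ML` with `df = p(p+1)/2 − free parameters`
(saturated models give chi-square 0 at df 0). Complete-case analysis is
used within each stratum. Strata are below/above-optimal water and
below-optimal N; above-optimal N is *reported as non-converged by design*
— data paucity in that stratum does not support a stable model, and the
package declines to force one. Because directly extracted NUE pairs are
scarce, the full three-response model often lacks complete cases in a
stratum; the analysis driver therefore also fits a reduced yield+WP model
on the much larger WP subset. Edge lists are editable config (YAML/JSON),
not hard-coded truth.

## Regression-tree ranking

A CART regression tree is grown by greedy variance reduction: node risk is
the node MSE weighted by the node's sample fraction; numeric splits sit at
midpoints between sorted distinct values; categorical features (including
the high-cardinality study identifier) are split by response-ordered
partitioning, which is optimal for squared error. Splitting stops at
`min_leaf = 5`, `max_depth = 12` (artifact defaults; no hyperparameters
are inherited from elsewhere) or zero gain, and ties break
deterministically toward the lowest feature index, then lowest threshold.
Missing feature values are imputed with the training-split median/mode
(surrogate splits are out of scope); prediction routes unseen categories
to the larger child. Accuracy is reported by seeded 10-fold
cross-validation (fold sizes differ by at most one, every observation
tested exactly once). Predictor importance is the sum over a feature's
splits of the risk change (parent risk minus the two child risks) divided
by the number of branch nodes; unused features score 0, and the root split
is verified against an exhaustive search over all (feature, threshold)
pairs, plus an independent CART implementation (`rpart`) as a
cross-check.

## Life-cycle characterization

The system boundary covers production and transport of N fertilizer, its
field emissions (N2O, NH3, NOx, nitrate leaching, derived as fertilizer
rate times emission coefficients) and the provision of irrigation water;
irrigation facilities, machinery and equipment are excluded. Impact scores
are the inventory-by-factor product over eight categories (GWP kg CO2 eq,
PED MJ, AP kg SO2 eq, ADP kg antimony eq, EP kg P3O4 eq, RI kg PM2.5 eq,
POFP kg NMVOC eq, ETx CTUe) with fixed units enforced at parse time;
substances missing from the factor matrix contribute zero and are listed
in a diagnostics attribute, while a unit disagreement is an error naming
the substance. The shipped factor matrix and emission coefficients are
**synthetic fixtures** (typical literature magnitudes, labelled as such in
their filenames): real analyses must supply their own matrices, and the
package does not claim to reproduce any published absolute per-hectare
score. What it does claim — and tests — is the arithmetic that depends
only on published numbers: per-tonne scaling by regional yield and
inter-region ratios.

## Economic valuation

Saved water is valued at `mm × 10 × price` (yuan/m^3; the factor 10 is
the same mm-to-m^3 conversion, confirmed by the published worked rows,
e.g. 49 mm × 0.30 yuan/m^3 × 10 = 147.00 yuan/ha), saved N at
`kg × price`, and avoided emissions at `kg CO2 × carbon price / 1000`.
The carbon share is the carbon value relative to the *input*-saving value
(the published East row, 0.89/41.30 = 2.15%, fixes this convention), and
is undefined — not zero — when the input value is 0. Computation keeps
full precision; the report layer rounds per-hectare values to 2 d.p.
first and derives totals, shares and regional scale-ups from the rounded
components, which is the convention the published tables follow. The
package stores the published regional inputs (prices, savings, avoided
GWP, areas) as reference tables and reproduces every row of both
valuation tables end-to-end in its test suite.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every stochastic claim in the package is
validated. It emulates the synthesized literature's structure:

* 126 studies, 3–13 pairs each (~1,000 yield pairs), regions drawn with
  weights 201/292/404/424 (the published per-region observation counts);
* region-specific true optima — water 316/359/289/557 mm and N
  240/240/195/270 kg/ha for Center/East/North/Northwest — and yields at
  the optimum of 7.4/7.6/6.5/5.1 t/ha;
* an asymmetric quadratic hump response: multiplier
  `1 − c·(x/opt − 1)^2` below the optimum and `1 − 0.4·c·(x/opt − 1)^2`
  above it, maximal exactly at the optimum. A plateau would make overuse
  costless, contradicting the hump-shaped responses the synthesis reports,
  so the above-optimum branch keeps a (gentler) penalty. Curvatures
  (`c_w = 0.6`, `c_n = 0.25`) were set so the overall simulated yield
  response ratio lands in the published range (several tens of percent);
* controls with rainfall-only water (0.35–0.55 of the optimum) and zero
  N; treatments spanning 0.45–1.5 (water) and 0.4–1.6 (N) of the optimum,
  so above-optimal strata exist;
* study-level random intercepts (`tau2 = 0.04`) and residual noise
  (`sigma2 = 0.02`) on the log response-ratio scale — log-scale noise so
  ratios are normally distributed, matching the pooling model; the
  magnitudes are typical of agronomic meta-analyses (between-study SD
  ~0.2, within-study SD ~0.14 on the log scale);
* soil covariates drawn per study, moderating the response linearly and
  positively (+0.05/+0.03/+0.04 per SD of SOC/AP/AK);
* ET rising much more slowly than water input (`ET = 200 + 0.25·w` mm),
  so treated WP increases alongside yield as in the literature;
  missing-completely-at-random field deletion calibrated to the published
  availability: ~43% of pairs have ET (and hence WP), ~8% have directly
  extracted NUE pairs (generated with a known offset around the yield
  response), and soil/climate fields are 5–30% missing.

What it does **not** emulate: real covariance between management choices
and site properties (inputs are drawn independently of soil and climate),
weather time series, non-random missingness, and publication bias. Tests
passing on this generator therefore validate the estimators under a
correctly specified model — they do not certify behaviour under the
confounding structure of real literature data.

## Numerical choices and validation problem sizes

* REML bisection: 60 halvings, numerical derivative step
  `1e-6·(lambda + 1e-3)`; degenerate dispersion (`sigma2 < 1e-14`)
  projects to `tau2 = 0`; single-study fits fix `lambda = 0`.
* Collinear path-model parents are rejected at condition number 1e10.
* Tree splits require gain above 1e-12; bin/argmax ties break toward lower
  input with relative tolerance 1e-8.
* Parameter recovery runs 200 replicates of 200-study panels: with `k`
  clusters the recovery pivot is approximately t-distributed with `k−1`
  degrees of freedom, and a fixed ±2·SE band only attains 95% coverage
  once `k` is large enough for the normal limit (P(|t_49| < 2) is 94.9%),
  so the panel size is chosen where the band's nominal level applies.
* Bootstrap coverage uses 1,000 replications of 30-study datasets at 999
  iterations each; the vectorized refits keep this to about two minutes.
* The grid-search REML oracle refines a 21×21 grid four times (resolution
  ~2.5e-5 on `tau2`), and agreement is asserted absolutely at 1e-4.

## Limitations

Optimum estimates are bin-resolution and sensitive to input-mix
confounding on noisy data; the replicate-based weights are a declared
substitution for unavailable sampling variances; the LCA fixtures are
synthetic; NUE effect sizes depend entirely on directly extracted pairs;
and all dataset-dependent headline numbers (overall percent changes,
regional saving potentials) are properties of whatever dataset is
supplied — on the synthetic generator they are parameter-recovery
analogues, not reproductions of published values.
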