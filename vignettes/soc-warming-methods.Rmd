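---
title: "Methods: space-for-time estimation of soil carbon responses to warming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: space-for-time estimation of soil carbon responses to warming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socsft)
```

## The problem and the approach

Long-term net changes of soil organic carbon (SOC) under climate warming
cannot be observed directly: SOC turnover plays out over decades to
millennia, while field warming experiments run for years. `socsft`
implements a hybrid of **space-for-time substitution** and
**random-effects meta-analysis**: sites that are alike in everything that
matters for SOC except temperature are treated as snapshots of the same
soil at different points of a warming trajectory, under the assumption
that both are at steady state with their current climate.

The pipeline is:

1. **Harmonize** layered profile measurements of SOC content to three
   standard depth intervals (0–0.3, 0.3–1, 1–2 m) with a mass-preserving
   spline, and convert to stocks.
2. **Group** profiles into 1 °C mean-annual-temperature (MAT) classes,
   subdivided by landform, soil order, precipitation seasonality and a
   50-mm mean-annual-precipitation (MAP) bin.
3. **Pair** each ambient class `[i, i+1)` with the warm class
   `[i+ΔT, i+ΔT+1)` for warming levels ΔT = 1…5 °C; a pair is one shared
   covariate group whose group-mean MAPs differ by less than 50 mm.
4. **Pool** the log response ratios lnRR = ln(warm mean / ambient mean)
   across pairs with inverse-variance weights `1/(v + τ²)`, back-transform
   to percentage change `(e^lnRR − 1)·100`, and regress the pooled
   percentages on ΔT.
5. **Interpret** the responses with a one-pool steady-state model with
   Q10 temperature scaling, and **rank moderators** with a case-weighted
   random forest ("meta-forest").

Negative lnRR means SOC loss under warming: the ratio is always
warm/ambient.

## The one-pool steady-state model

A single carbon pool obeys `dC/dt = I − kC`, so the steady state is
`C = I/k`. Scaling decay with temperature as `k_w = k·Q10^(ΔT/10)` and
letting inputs change by a factor `I_w/I` gives the relative steady-state
response

```
R = (I_w/I) · Q10^(−ΔT/10) − 1,
```

implemented in `steady_state_response()` (in percent). Carbon-input
scenarios compound multiplicatively, `I_w/I = (1 + r)^ΔT`
(`input_ratio()`); the compound form is the one under which the fitted
Q10 obeys the exact identity `q10(r) = q10(0)·(1+r)^10`, which ties the
no-input-change and input-increase parameterisations of the same response
curve together and is asserted to numerical precision in the tests.
`fit_q10()` minimises the sum of squared differences between observed and
modelled percentage responses over Q10 ∈ [1, 10] (one-dimensional bounded
least squares, tolerance 1e−8). The fit is unweighted by default; the
`weights` argument exposes precision-weighting for users who prefer to
weight the per-level means by their confidence.

## Effect sizes and pooling

The within-comparison sampling variance of lnRR uses the standard
delta-method form `v = sd_w²/(n_w·mean_w²) + sd_a²/(n_a·mean_a²)`; this
is the default the usual mixed-effects meta-analytic machinery assumes.
Between-comparison variance τ² is estimated by REML (via
`metafor::rma.uni`, with a damped-step retry and a DerSimonian–Laird
fallback for the rare sets on which Fisher scoring stalls);
a closed-form DerSimonian–Laird estimator is available as an option.
Confidence intervals use normal quantiles (±1.96 se). Degenerate effects
— zero variance (both group sds zero) or a non-positive group mean — are
dropped with a diagnostic rather than given infinite weight.

Moderator analyses pool each level of a categorical moderator under a
shared τ² (estimated in the mixed-effects model with the moderator as the
only fixed effect) and test between-level heterogeneity with the
subgroup statistic `QM = Σ_l W_l (μ_l − μ̄)²` on `levels − 1` degrees of
freedom.

## Harmonization: the mass-preserving spline

Layer-support measurements (means over `[top, bottom)`) cannot be
compared across profiles with differing horizons. `fit_mp_spline()` fits
a piecewise-quadratic depth function f, continuous with continuous first
derivative (gaps between non-contiguous layers get their own bridging
piece), minimising

```
(1/n) Σ_i (y_i − mean of f over layer i)²  +  λ ∫ f′(x)² dx .
```

This is a linearly-constrained quadratic program solved exactly through
its KKT system in base R — no iteration, no tuning, fully deterministic.
Standard-interval means come from analytic integration of the quadratic
pieces (`mean_over()`, `harmonize()`).

Numerical conventions:

* **λ defaults to 0.1** and follows the centimetre-depth convention of
  the equal-area-spline literature (the roughness integral is per cm of
  depth even though the package stores depths in metres). Under this
  convention the default reproduces observed layer means to well within
  1% on smooth profiles; λ → 0 approaches exact interpolation of the
  layer means.
* **No extrapolation**: intervals beyond the deepest observed layer are
  `NA`; partially covered intervals carry the mean over the covered part
  with `coverage = FALSE`, and the pairing stage uses fully covered
  intervals only.
* Depths are metres, positive downward, half-open `[top, bottom)`.

Bulk density and gravel are aggregated to standard intervals as
thickness-weighted means of the observed layers; stocks then follow
`SOC_s = SOC_c/1000 · D · BD · (1 − G/100)` (kg C m⁻², with SOC_c in
g C kg⁻¹, D in m, BD in kg m⁻³). The `/1000` is the dimensionally
consistent mass-fraction conversion for these units; conventions that
write `/100` implicitly use D in cm or BD in g cm⁻³. Multiply by 10 for
Mg C ha⁻¹.

## Missing bulk density and gravel

Real profile archives typically lack BD and gravel for most records.
`impute_missing()` trains gradient-boosted regression trees (xgboost, 200
rounds, depth 4, learning rate 0.1, single-threaded and seeded, no
subsampling so the fit is exactly reproducible) on the complete cases,
using depth geometry, SOC content, the sibling property and, when
available, site covariates. Imputed gravel is clamped to [0, 100] %,
imputed BD to a plausible range (default 50–2700 kg m⁻³). A held-out
fifth of the complete cases yields the reported out-of-sample RMSE.
Imputation is one-shot — no chained multiple imputation — which keeps the
pipeline deterministic; observed values are never altered, and at least
30 complete cases are required.

## Precipitation seasonality

The precipitation concentration index `PCI = 100·Σp_i²/(Σp_i)²` over 12
monthly totals ranges from 100/12 (≈ 8.333, uniform) to 100 (single
month). A site is classed "uniform" when mean PCI falls below the
threshold (default 8.3), otherwise "summer" or "winter" by comparing the
April–September and October–March totals (reversed in the southern
hemisphere); exact ties are classed winter, a documented tie-break.
Note the quirk: because the analytic minimum of PCI (≈ 8.333) exceeds the
conventional 8.3 threshold, the uniform class is unattainable at the
default — the threshold is configurable for users who want it attainable,
and the package does not silently change the convention.

## The synthetic world: known ground truth

`generate_world()` builds a miniature global profile archive in which the
true answer is known exactly: per standard layer, expected SOC stock is
`I_l / (k0_l · Q10_l^(MAT/10))` — the steady state of the one-pool model
— times lognormal noise (mean 1, configured CV). True responses to any
warming are then available in closed form (`true_response()`), so the
whole pipeline can be validated end to end.

Default conditions, chosen once as the package's study conditions:

* **n = 2000 profiles**, MAT uniform on [0, 10) °C — uniform sampling
  guarantees every 1 °C class is populated; a bimodal mode mimics the
  latitudinal clustering of real archives.
* **MAP uniform on [400, 600) mm** — four 50-mm bins, narrow enough that
  matched pairs exist in quantity at n = 2000.
* **True Q10 = 1.7 / 1.4 / 1.2** by layer with inputs and base decay
  declining with depth (I = 0.20/0.10/0.04 kg C m⁻² yr⁻¹,
  k0 = 0.020/0.010/0.005 yr⁻¹), giving realistically depth-decaying
  content (roughly 27 → 7 g C kg⁻¹).
* **Noise CV 0.3** — multiplicative lognormal, because SOC is positive
  and right-skewed and lnRR of lognormal group means is approximately
  normal, matching the meta-analysis assumptions.
* **10% missingness** in BD and gravel; **10% cropland** with a fixed
  0.8 depletion factor so the cropland-exclusion sensitivity analysis has
  signal to find.
* Three monthly-precipitation archetypes (summer-peaked, winter-peaked,
  uniform at exactly MAP/12) with weights 0.4/0.3/0.3; horizon boundaries
  drawn randomly within 0–2 m so harmonization is genuinely exercised.

What the generator does **not** emulate: spatial autocorrelation,
paleoclimate legacies, land-use history beyond the cropland flag,
disturbance (fire, erosion), soil-vs-air temperature decoupling, or any
correlation between MAT and MAP. Passing tests therefore demonstrate the
statistical machinery is correct and unbiased under the stated model —
not that real-world confounding is absent.

A note on harmonization bias: the generator's content is piecewise
constant across the standard layers while observed horizons are drawn
independently of those boundaries, so the per-profile smooth
reconstruction carries a small systematic bias (a few percent). It is
shared by ambient and warm groups and cancels in the response ratios,
which is precisely the property the paired design is meant to deliver;
the recovery test (below) confirms the cancellation.

## The meta-forest

`fit_metaforest()` regresses effect sizes on environmental moderators
with a random forest whose cases carry meta-analytic weights
`w = 1/(v + τ²)` as bootstrap sampling probabilities (ranger), so precise
comparisons shape both the resampling and the split losses computed on
the resampled trees. Hyperparameters come from k-fold cross-validation
(default 5 folds) over a small declared grid: trees {250, 500}, candidate
predictors per split {⌈p/3⌉, ⌈√p⌉}, minimum leaf {3, 5}. Variable
importance is impurity (variance-reduction) importance — the summed
squared-error improvement of all splits on a predictor, averaged over
trees — normalised to sum to 1. Per-row prediction uncertainty is the
standard deviation of the individual tree predictions; rows with
categorical levels unseen in training are flagged and returned `NA`
rather than silently coerced. Constant outcomes and fewer than 30
effects are refused. The moderator set is configurable; the standard
list covers baseline SOC, soil order, depth, MAT, MAP, aridity, PCI,
summer-precipitation fraction, ΔT, ΔMAP, elevation, landform, NPP and
biome.

## Validation and problem sizes

The test suite validates every stage against independent oracles: dense
grid search for `fit_q10`, from-scratch reimplementation of the weighted
pooling formulas, hand-computed DerSimonian–Laird values, Riemann
integration of the fitted spline, exhaustive enumeration of a toy pairing
world, and `metafor` as an external cross-check of τ² and pooled means.
End-to-end, 20 replicate synthetic worlds (n = 2000, noise CV 0.3, true
topsoil Q10 = 1.7) are run through imputation → harmonization → pairing
→ pooling, and the pooled 1 °C topsoil response's 95% CI must cover the
analytic −5.17% in at least 90% of replicates. These sizes keep the full
suite at a few minutes on one core while leaving the statistics
well-resolved (≈ 300–350 pairs per replicate).

## Known limitations

* Steady-state assumption throughout; transient trajectories and
  multi-pool models are out of scope.
* One profile can appear in pairs at several warming levels; levels are
  analysed separately and no cross-level independence correction is
  applied.
* The MAP group bins are fixed 50-mm bins; the explicit group-mean
  difference test (< 50 mm, or 25 mm for the sensitivity variant)
  enforces the matching criterion regardless of binning.
* Imputation is single-pass: imputation uncertainty is not propagated
  into the meta-analytic variances.
* The meta-forest carries weights through resampling only; the split
  criterion itself is unweighted, which matches the behaviour of the
  standard weighted-bootstrap implementations.
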