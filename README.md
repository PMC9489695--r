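# socsft

Depth-resolved steady-state responses of soil organic carbon (SOC) to
climate warming, estimated by a hybrid of **space-for-time substitution**
and **random-effects meta-analysis**.

## The problem

Whether soils gain or lose carbon under a warmer climate is governed by
turnover that takes decades to millennia — far beyond the reach of field
warming experiments. Space-for-time substitution sidesteps the waiting:
sites that share landform, soil type, precipitation amount and
seasonality, but sit in mean-annual-temperature (MAT) classes ΔT degrees
apart, are treated as two steady states of the same soil separated by
ΔT °C of warming. Comparing matched "ambient" and "warm" groups across a
large profile archive yields the percentage SOC change per warming level,
separately for the 0–0.3, 0.3–1 and 1–2 m depth layers.

## What the package does

* **Harmonization** — a mass-preserving (equal-area) spline fits each
  profile's layer-mean SOC content and integrates it over the standard
  depth intervals; stocks follow
  `SOC_s = SOC_c/1000 · D · BD · (1 − G/100)` (kg C m⁻²).
* **Imputation** — missing bulk density and gravel are filled with
  boosted regression trees trained on complete cases (seeded,
  deterministic, with held-out RMSE).
* **Grouping and pairing** — 1 °C MAT classes; groups matched on
  landform, soil order, 50-mm MAP bin and precipitation seasonality
  (from the precipitation concentration index,
  `PCI = 100·Σp²/(Σp)²`); pairs require group-mean MAP difference
  < 50 mm.
* **Meta-analysis** — log response ratios `lnRR = ln(SOC_w/SOC_a)` with
  delta-method variances, REML (or DerSimonian–Laird) τ², pooling with
  weights `1/(v + τ²)`, back-transform `(e^lnRR − 1)·100`, moderator QM
  tests, and regression of the pooled response on warming level.
* **One-pool Q10 model** — at steady state `C = I/k` with
  `k_w = k·Q10^(ΔT/10)`, the response is
  `R = (I_w/I)·Q10^(−ΔT/10) − 1`; `fit_q10()` inverts estimated
  responses into a temperature sensitivity, under fixed or compound
  (`(1+r)^ΔT`) carbon-input scenarios.
* **Meta-forest** — a case-weighted random forest over the effect sizes
  ranks environmental moderators and predicts gridded responses with
  across-tree uncertainty.
* **Synthetic world** — a generator with a known per-layer Q10 law and
  configurable noise, missingness and covariates provides ground truth
  for end-to-end validation, and is itself part of the tested surface.

## Worked example

```r
library(socsft)

w <- generate_world(world_config(n_profiles = 2000, seed = 42))
res <- run_sft_pipeline(w$profiles, w$environments,
                        layer = "0-0.3", warming_levels = 1:5)
res
#> Space-for-time SOC response (soc_s, layer 0-0.3)
#>   +1 degC: -5.51% (95% CI -8.17 to -2.76), k = 316
#>   +2 degC: -10.11% (95% CI -12.87 to -7.27), k = 278
#>   +3 degC: -13.73% (95% CI -16.59 to -10.77), k = 241
#>   +4 degC: -16.55% (95% CI -19.41 to -13.59), k = 213
#>   +5 degC: -20.59% (95% CI -23.71 to -17.35), k = 180
```

The synthetic world was built with a true topsoil Q10 of 1.7, whose
analytic 1 °C steady-state response is
`true_response(w, "0-0.3", 1)` = −5.17%: the pooled estimate at +1 °C
(−5.51%, CI −8.17 to −2.76) covers it, and each additional degree of
warming deepens the loss roughly linearly (`res$regression$slope` ≈
−3.7% per °C here). Fitting the one-pool model back onto the five pooled
responses recovers the temperature sensitivity:

```r
pcts <- vapply(res$pooled, function(p) p$percent_change, numeric(1))
fit_q10(as.numeric(names(pcts)), pcts)
#> One-pool steady-state Q10 fit
#>   Q10 = 1.6048 (bounds 1-10)
#>   carbon-input change: +0.0% per degC (compound)
#>   SSE = 2.904 over 5 response points
```

i.e. a fitted Q10 of 1.60 against the true 1.7, from one noisy replicate
of 2000 profiles. `vignettes/soc-warming-methods.Rmd` documents the
model, the matching rules, all numerical conventions and the generator's
assumptions.

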