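# esval

Benefit-transfer ecosystem service valuation for categorical land-cover
maps, with the Bench-Sheko zone (southwestern Ethiopia) — a corridor of the
Eastern Afromontane biodiversity hotspot — as the packaged worked case.

Conservation planning needs the monetary worth of what a landscape's
vegetation does: nutrient cycling and pollination, climate regulation
through carbon storage, food and raw-material provisioning, recreation and
cultural value. Measuring those directly is rarely feasible at the scale of
a whole administrative zone, so practitioners transfer per-hectare unit
values from comparable study sites and multiply them by mapped class areas.
`esval` implements that pipeline end to end for anyone working from a
classified map: ecologists and resource economists valuing a landscape,
and remote-sensing analysts who need the accuracy bookkeeping that goes
with the map.

## The model

With `A_k` the area (ha) of land-cover class `k` and `VC_kf` the annual
per-hectare value coefficient of service function `f` in class `k`
(USD ha⁻¹ yr⁻¹):

```
ESV_k = Σ_f A_k · VC_kf          value of class k
ESV_f = Σ_k A_k · VC_kf          value of service function f
ESV   = Σ_k Σ_f A_k · VC_kf      total ecosystem service value
```

Coefficients come from three sources, all assembled by the package:

* **Value transfer** — a published unit value times an explicit
  inflation/price adjustment factor.
* **Carbon chain** — per-class carbon stock `S` (t C ha⁻¹) priced through
  the social cost of carbon: `VC = S · (44/12) · SCC`, with 44/12 the exact
  CO₂/C molar mass ratio and SCC in USD per t CO₂ (default 1.47).
* **Direct market value** — e.g. coffee:
  `NPV = rate · price · (1 − cost_fraction)`.

The sensitivity of the result to any class's coefficients is the elasticity

```
CS = | (ΔESV / ESV) / (ΔVC / VC) |
```

under a uniform ±50% perturbation of that class's coefficients. Because ESV
is linear in the coefficients, CS ≡ 1 when ESV is read as the class's own
value (complete elasticity, the conventional report), and CS equals the
class's share of the total when ESV is read as the grand total — both modes
are implemented.

The package also covers the map-side quality control: NDVI
(`(NIR − red)/(NIR + red)`) and per-class NDVI statistics, per-class area
accounting, and thematic accuracy assessment (confusion matrix, overall
accuracy, Cohen's kappa, producer's and user's accuracy). A seeded
synthetic-landscape generator (multinomial class composition, paired
NIR/red bands hitting prescribed per-class NDVI means, reference points
with a prescribed confusion structure) makes every stage testable without
satellite imagery.

## Worked example

```r
library(esval)

areas <- load_area_table("esv")       # published per-class areas (ha)
vc    <- load_coefficient_table()     # adjusted USD/ha/yr coefficients
report <- esv_total(areas, vc)
print(report)
#> Ecosystem service valuation
#>   total: 2.089 billion USD / yr
#>   by class (million USD / yr):
#>     coffee_plantation       269.784
#>     disturbed_forest        128.081
#>     farmland                225.152
#>     grassland                78.158
#>     remnant_forest          882.738
#>     savanna                 334.169
#>     wetland                 170.979
```

The landscape provides about 2.089 billion USD of ecosystem services per
year; remnant forest contributes the most in absolute terms (it is the
largest class), while wetlands carry the highest per-hectare coefficient
(9,294.3 USD ha⁻¹ yr⁻¹, dominated by water treatment and cultural value):

```r
class_total_coefficients(vc)[c("wetland", "remnant_forest")]
#>        wetland remnant_forest
#>         9294.3         6007.9

sensitivity_coefficient(areas, vc, "wetland", delta = 0.5)$cs
#> [1] 1
```

A coefficient of sensitivity of 1 means the valuation responds exactly
proportionally to any coefficient revision — the linear benefit-transfer
model has no leverage points hiding in it.

The carbon chain alone, over the carbon-survey area set:

```r
res <- run_pipeline(run_config("carbon", quiet = TRUE))
sum(res$carbon$total_usd_yr) / 1e6
#> [1] 722.3327
```

`run_pipeline()` ties the stages together (areas → coefficients → ESV →
sensitivity) and, given `out_dir`, writes the area, coefficient, ESV,
carbon and sensitivity tables as CSV plus a JSON summary, byte-identically
for a fixed configuration and seed.

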