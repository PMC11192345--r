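---
title: "Methods: benefit-transfer valuation of a land-cover map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benefit-transfer valuation of a land-cover map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esval)
```

## The valuation model

`esval` computes the annual monetary value of the ecosystem services of a
categorical landscape by benefit transfer. The model is a bilinear form in
two inputs: the per-class areas $A_k$ (hectares) and a table of per-hectare
annual value coefficients $VC_{kf}$ (USD ha$^{-1}$ yr$^{-1}$), one per
(land-cover class $k$, service function $f$) pair:

$$\mathrm{ESV}_k = \sum_f A_k \, VC_{kf}, \qquad
  \mathrm{ESV}_f = \sum_k A_k \, VC_{kf}, \qquad
  \mathrm{ESV} = \sum_k \sum_f A_k \, VC_{kf}.$$

The assumptions are those of any benefit-transfer exercise: services scale
linearly with area, classes are internally homogeneous, and unit values
estimated at comparable study sites remain valid at the policy site after
an explicit price adjustment. None of these is tested by the package; they
are what the method *is*. What the package does guarantee is the
arithmetic: the total always equals both marginal sums (verified by a
property test against a brute-force double loop on random instances), and
the whole computation is linear, so scaling areas or coefficients scales
the result.

A (class, function) pair absent from the coefficient table means "service
not provided" and contributes zero. This follows the source tables, where
blanks are meaningful — e.g. farmland carries no cultural coefficient.

## Coefficient sources

`assemble_coefficient_table()` unions three kinds of entries and rejects
duplicate (class, service) keys:

* **Transferred values.** `adjusted = original × factor`, with the factor
  supplied per record. We deliberately do not implement a price-index
  lookup: the source studies span different years and deflators (the
  implied factors in the packaged tables range from 1.0 to ~2.08), and no
  single index reproduces them. The printed original/adjusted pairs ship as
  fixtures (`load_value_transfer()`), so the adjustment is data, not code.
* **Carbon chain.** Stock $S$ (t C ha$^{-1}$) → CO$_2$ equivalent
  $S \times 44/12$ → annual value $\times$ SCC (USD per t CO$_2$, default
  1.47, an annualized social-cost estimate for 2021/22). The exact molar
  ratio 44/12 is used rather than the 3.67 shorthand: it reproduces every
  packaged CO$_2$-equivalent entry to 2 decimal places, which 3.67 does
  not.
* **Direct market values.** Coffee:
  $\mathrm{NPV} = \mathrm{rate} \times \mathrm{price} \times
  (1 - \mathrm{cost\ fraction})$, defaults 0.84 t ha$^{-1}$ yr$^{-1}$,
  4,685 USD t$^{-1}$ and 0.13. With these inputs the chain gives 3,423.80
  USD ha$^{-1}$ yr$^{-1}$; the source table prints 3,423.57, an 0.007%
  discrepancy whose origin is not stated there. We report the computed
  value and treat the printed one as agreeing to well under 1%.

All arithmetic is kept at full precision; rounding (2 dp for per-hectare
values, 3 dp for millions/billions) happens only at serialization.

## Two area tables, never reconciled

The published record contains two per-class area sets for the same
landscape that disagree (remnant forest 146,251.59 vs 146,929.5 ha, and a
savanna entry that differs fourfold), one printed with the carbon totals
and one with the ESV totals. `load_area_table("carbon")` and
`load_area_table("esv")` ship both verbatim; the pipeline takes areas as
input data and a run's configuration names which set it uses. The carbon
set is declared over the full 472,118-ha study extent (it omits the
built-up class), so its proportions deliberately sum to less than 1.

## Sensitivity

The coefficient of sensitivity is the elasticity of ESV with respect to a
uniform $(1+\delta)$ scaling of one class's coefficients, conventionally
$\delta = \pm 0.5$:

$$CS = \left| \frac{(\mathrm{ESV}_j - \mathrm{ESV}_i)/\mathrm{ESV}_i}
                   {(VC_j - VC_i)/VC_i} \right|.$$

Which ESV appears here is ambiguous in the literature. Read as the target
class's own ESV (`mode = "per_class"`, the default), linearity makes
$CS \equiv 1$ for every class and every $\delta \neq 0$ — complete
elasticity, the conventionally reported result, and an exact analytic
identity rather than a numerical finding. Read as the grand total
(`mode = "total"`), $CS$ equals the class's share of total ESV,
independent of $\delta$, lying in $[0,1]$ and summing to 1 across classes
— the more informative variant, since it ranks classes by how much the
total depends on their coefficients. Both are implemented; the default
preserves the conventional reading while `total` exposes the ranking.

```{r}
areas <- load_area_table("esv")
vc <- load_coefficient_table()
sensitivity_all_classes(areas, vc, mode = "total")[, c("class", "cs")]
```

## Map-side metrics

NDVI is the cellwise normalized difference $(NIR - red)/(NIR + red)$,
bounded in $[-1, 1]$ for nonnegative bands. Cells with $NIR + red = 0$
are undefined and masked as `NA` rather than set to 0, which would bias
class means toward zero. Areas use the fixed conversion 1 ha = 10,000
m$^2$ from a single square pixel size; there is no geodesic correction,
reprojection or resampling — the published areas are flat hectares.

Accuracy assessment uses the conventional remote-sensing confusion-matrix
layout: rows are map labels, columns reference labels, so user's accuracy
is the diagonal over row totals and producer's accuracy the diagonal over
column totals. Cohen's kappa is $(p_o - p_e)/(1 - p_e)$; it is undefined
when all counts fall in one cell and the package errors rather than
returning a conventional value. Per-class metrics for empty rows or
columns are `NA`, never 0. The test suite checks kappa and overall
accuracy against an independent reference implementation
(`e1071::classAgreement`) on random matrices to 1e-12. Variance estimates
and area-weighted (Olofsson-style) accuracy are out of scope: the source
workflow uses plain counts.

## The synthetic landscape generator

The generator exists so the full pipeline — areas, NDVI, accuracy,
valuation — can be exercised and tested without the original imagery or
field campaign, which are not reproducible at desk scale. It emulates
three things, each against a published target:

* **Class composition.** Cells are drawn i.i.d. multinomial at the
  published eight-class proportions (remnant forest 0.3098 … built-up
  0.0037; the printed values sum to 1.0001 from rounding and are
  renormalized). Realized proportions converge at $O(1/\sqrt{n})$, and
  tests assert recovery within 3 multinomial standard errors.
* **Spectral bands.** Per pixel, an NDVI value $v$ is drawn from a
  Gaussian at the class's target mean, truncated to $(-0.999, 0.999)$;
  the red band is a fixed reflectance (default 0.08) and the NIR band is
  solved as $red\,(1+v)/(1-v)$. Sampling the index and solving for the
  band — rather than adding noise to the bands — makes the per-pixel NDVI
  distribution exactly the target distribution and keeps both bands
  strictly positive, so NDVI cannot leave $(-1, 1)$. Published per-class
  NDVI means are the defaults; no per-class variance is published, so the
  default sd of 0.05 is our choice of a typical within-class spread at
  10 m resolution, documented as arbitrary.
* **Reference points.** Each class contributes a fixed number of points
  (default 100, the usual minimum recommendation for large complex areas)
  whose map labels are drawn from prescribed row-stochastic confusion
  rows, so accuracy metrics can be checked against known ground truth
  within binomial error.

Spatial structure is i.i.d. by default because the valuation depends only
on areas. An optional patch mode (`patch_size`) places uniform random seed
cells, labels them i.i.d. multinomial, and assigns every cell its nearest
seed's label: each cell's label is then marginally multinomial, so
expected proportions stay exactly at target while neighbours become
correlated. (A majority filter was considered and rejected: it provably
drifts composition toward the majority class.) The generator does not
simulate radiometry, clouds, shadows, atmosphere, georeferencing or
classifier behaviour — so passing tests show the *pipeline arithmetic* is
right, not that any classifier would reach a particular accuracy on real
scenes.

All randomness flows from one integer seed per call; sub-streams are
derived deterministically, and identical spec + seed gives bit-identical
output without disturbing the caller's RNG state.

## Problem sizes and numerical choices

The valuation itself is a handful of sums over a 7-class × ~20-service
table and runs in milliseconds. Statistical recovery tests use grids from
100×100 to 1000×1000 cells and 1,000–2,000 reference points per class —
large enough that 3-standard-error bands are tight (a percentage point or
two), small enough that the whole suite runs in well under a minute.
Validation tolerances follow the data's precision: proportions must sum
to 1 within 1e-9, marginal-consistency identities hold to 1e-9 relative,
and comparisons against published table entries are made at their printed
precision (2 dp). Raster I/O uses the plain-text ESRI ASCII grid format;
the in-memory containers are ordinary matrices with (row, col) indexing,
row 1 at the top.

## Known limitations

Benefit transfer inherits the transfer errors of its sources; the package
propagates, but cannot correct, disagreements between the printed tables
(it ships them verbatim and lets the configuration choose). No original
valuation (willingness-to-pay, avoided cost) is performed, no currency
conversion or discounting beyond the supplied multipliers, no Monte-Carlo
propagation of coefficient uncertainty, and no map production: the
classifier that makes the land-cover map is upstream of this package.
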