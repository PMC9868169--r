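---
title: "Methods: scoring, combining and analyzing human disturbance surfaces"
author: "hdindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, combining and analyzing human disturbance surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdindex)
```

## The model

The Human Disturbances Index treats anthropogenic pressure on a landscape
cell as the sum of three separately measured components:

$$\mathrm{HDI} = \mathrm{LNI} + \mathrm{RCI} + \mathrm{PEI}$$

Each scored dataset contributes an integer 0–10, so the components are
bounded by the number of datasets behind them: LNI (one dataset, land-use
naturalness) ≤ 10, RCI (water + energy consumption) ≤ 20, PEI (CO₂ + N₂O +
non-point pollution) ≤ 30, and HDI ∈ [0, 60]. All datasets are equally
weighted; `sumLayers()` accepts other weights, but the default — and the
validated range checks in `combineHdi()` — assume equal weighting.

The model's central assumptions are: (i) disturbance sources are additive
and exchangeable after standardization — a cell scoring 8 on energy use and
0 on emissions is as disturbed as one scoring 0 and 8; (ii) sectoral
consumption is uniform per unit area within the land-use classes that
generate it; and (iii) one projected CRS in meters underlies every input,
because centroid displacements and distance-band neighborhoods are computed
from cell-center coordinates (cell $(i,j)$, 0-based, has center
$x = x_0 + (j + 0.5)s$, $y = y_0 - (i + 0.5)s$ for cell size $s$).

## Naturalness (LNI)

Naturalness scores per class follow the HAILS evaluation: the operative
table (`defaultNaturalnessTable()`) gives arable 2, forest 0.67, grassland
1.33, artificial water 6, natural water 0, urban/rural/industrial 10,
unused 0. `hailsClassificationTable()` ships the underlying two-tier
classification (categories CS1–CS3, FCS1–FCS5) with its own 0–2 scores as
metadata. The two scales are deliberately not reconciled: the 0–10 table is
what enters the index, the 0–2 scheme documents the classification signs.
Both are plain data frames, user-overridable (and CSV-serializable) for
transfer to other regions.

```{r}
defaultNaturalnessTable()[, c("class", "score")]
```

## Consumption surfaces (RCI)

Sectoral totals are spatialized by the sector map
(`defaultSectorMap()`): agriculture onto arable land, industry onto
industrial land, urban public services onto urban land, forestry and
husbandry onto forest + grassland proportionally to area, and transport
energy over urban, rural and industrial land jointly — transport is not
confined to roadways, so it is spread over all built-up classes. Resident
sectors are rate-based: population density (persons/km²) times a per-capita
rate, urban and rural separately; their table totals, if present, are *not*
re-allocated by area (that would double-count), which the function reports.
A sector that is neither mapped nor explicitly ignored is an error, never a
silent drop.

Every allocation is a density (quantity/km²) and integrates back to its
input total to 1e-9 relative — the suite property-tests this conservation on
100 random landscapes. When regional totals and a zone raster are supplied,
allocation runs zone by zone and mosaics the results.

Electricity and fossil fuels are converted to standard coal equivalent
(tce) with a configurable factor table (`defaultFuelConversionTable()`,
national-standard conventions; factors are inputs, not constants of the
method). Statistics are averaged over explicit year windows
(`temporalAverage()`), matching the convention of 5-year blocks with a
trailing 3-year block (2016–2018); making the window an explicit year set
avoids encoding either convention.

## Emission surfaces (PEI)

Coarse emission fields are upsampled with ordinary kriging: an exponential
variogram $\gamma(h) = c\,(1 - e^{-h/a})$ with zero nugget is fitted to the
binned empirical semivariogram by weighted least squares (Cressie weights
$N_b/\gamma^2$), and the kriging system is solved once per field with all
prediction points as right-hand sides. Zero nugget makes the interpolator
exact at sample locations. Numerical choices: constant fields short-circuit
to a constant surface; a singular system falls back to inverse-distance
weighting (power 2) with a warning; negative artifacts are clamped to zero
with a message, since emissions are non-negative; fields above 600 samples
are thinned before the dense solve.

Non-point pollution is confined to arable and rural land: rural cells emit
population density × per-capita emission; arable cells emit the fertilizer
application rate × (1 − effective use rate); every other class is exactly 0
(a hard invariant, property-tested on random landscapes). The published
decomposition of these two drivers is not printed anywhere we could follow,
so this product form is the package's interpretation — it is monotone in
each driver and reduces to zero at full fertilizer efficiency. The
non-point surface enters scoring through its land-cover indicator
(`landCoverIndicator()`), a min-max rescale to [0, 1] that is invariant
under positive affine rescaling of the raw surface; the full potential
non-point pollution index with distance, runoff and slope indicators is out
of scope, as it would require DEM and soil inputs.

## Standardization and classification

Raw surfaces are standardized by Fisher–Jenks natural breaks
(`jenksBreaks()`): the exact dynamic program over distinct values with
multiplicities, so ties never split across classes and the result is
deterministic. Two decisions reconcile the nominal 0–10 scale with k
classes: exact-zero cells (no activity — e.g. consumption on natural water)
score 0, and the k = 10 Jenks classes map to integers 1–10. Breaks are
computed once on values pooled across all periods of a variable, so a given
raw value receives the same score in every period; the suite checks this
pooling consistency and the within-period monotonicity it implies. Breaks
persist as JSON sidecars (`writeBreaks()`/`readBreaks()`) for reproducible
re-scoring.

Bins are half-open on the right, $(b_{i-1}, b_i]$, first bin closed; a value
exactly on a boundary goes to the lower class (deterministic tie-break).
For large rasters the DP runs on 2048 quantile bins (bin means with
counts); `exact = TRUE` forces the full computation, and the test suite
checks >98 % classification agreement between the two paths as well as
exact equality of the DP with exhaustive partition enumeration at small n.
Degenerate pooled distributions (fewer distinct values than classes) fall
back to equal-interval breaks with a warning; a constant nonzero pool maps
to class 1.

`classifyLevels()` cuts HDI into ten width-6 levels, level I = [0, 6],
level n = (6(n−1), 6n], reproducing the integer table 0–6, 7–12, …, 55–60
exhaustively (tested on every integer). `tabulateLevels()` reports
percentage shares per zone that sum to 100 exactly before rounding, with an
optional two-decimal rounding emulation for comparison against published
tables.

## Spatial statistics

**Centroid.** The HDI-weighted centroid
$X = \sum x_{ij}\,\mathrm{HDI}_{ij} / \sum \mathrm{HDI}_{ij}$ (likewise
$Y$) uses cell centers; it is invariant under positive rescaling of HDI and
equivariant under origin translation (both property-tested).
`centroidTrack()` reports per-segment Euclidean displacement, compass
bearing (clockwise from north, plus an 8-sector cardinal label to echo
"southwest"-style prose), and speed = displacement / actual interval years.
Where a published speed implies division by a nominal 5-year interval over
a 3-year span, this package divides by the actual span and documents the
difference rather than emulating it.

**Moran's I.** $I = \sum_i\sum_j W_{ij}(x_i-\bar x)(x_j-\bar x) /
(S^2 \sum_i\sum_j W_{ij})$ with $S^2$ the population variance (divide by
n) — this normalization yields the exact analytic value $I = -1$ on a
rook-weighted checkerboard, which the suite asserts identically. The
weights scheme behind published basin-scale values is not stated anywhere,
so the package defaults to binary queen contiguity with no row
standardization (the double-sum formula taken literally) and exposes rook
and distance-band alternatives. Inference: normality-assumption variance
with $E[I] = -1/(n-1)$ by default, seeded permutation (default 999) as a
check — the permutation mean is verified against $-1/(n-1)$ within 3
standard errors at 10,000 shuffles.

**Getis-Ord Gi\*.** $G_i^* = \sum_j W_{ij}(d)x_j / \sum_j x_j$ with binary
distance-band weights *including* the self term ($W_{ii}=1$; the starred
statistic). The z-score uses the standard Gi* moments under the
randomization null; categories at the usual thresholds ±1.645/±1.960/±2.576
(90/95/99 %). Default band d = 2 cell sizes. A constant field gets Z = 0
and `not_significant` everywhere by convention (logged). Recovery is
validated on planted clusters: discs raised 3 background-SD are flagged
hot95-or-stronger on ≥ 90 % of their cells.

## Synthetic landscapes

The generator emulates the pipeline's input kinds, not any real region:
land use is a Gaussian-smoothed uniform noise field thresholded at the
cumulative class-proportion quantiles (rank-based, so class shares match
proportions to within one cell; `clusteringStrength` is the smoothing sd in
cells, 0 = spatially random — join counts verify both regimes); population
is lognormal on settlement cells (defaults 2500 persons/km² urban, 400
rural, zero elsewhere — urban an order of magnitude above rural, with the
basin-scale average in the hundreds); sector statistics follow a
multiplicative trend (default 1.05/period) with small lognormal noise;
emission fields are smooth lognormal surfaces on a 4× coarser grid
(emulating a coarse global inventory) with optional planted clusters whose
ground-truth masks are returned. The default scenario is a 100×100 grid of
1 km cells with seven periods labeled 1990–2018 (exercising both averaging
conventions) and an arable-dominated mix (55 % arable, 20 % settlement);
one seed determines the entire bundle bit-identically.

What passing tests on these landscapes do *not* show: real land-use
mosaics have long-range structure, population is not lognormal-iid within
classes, real sector statistics carry reporting artifacts, and real
emission inventories are not smooth lognormal fields. The synthetic tests
validate the *mechanics* (conservation, monotonicity, determinism,
recovery of planted structure), not regional realism.

## Problem sizes and runtime choices

The shipped tests run on grids from 2×2 (enumerable oracles) to 60×60, with
brute-force O(n²) comparisons capped at 20×20 and the permutation-null
check at a 5×5 field with 10,000 shuffles; the pipeline smoke test uses a
30×30, three-period scenario. These sizes were chosen so every oracle is
exhaustively checkable while the full suite stays interactive; the
implementation itself is vectorized (sparse weights, single kriging solve,
binned Jenks) and comfortably handles the 100×100 default scenario.

## Known limitations

- Raster I/O is ESRI ASCII grid only; CRS is an opaque label and the
  toolkit never reprojects or validates projections.
- The kriging fit is a single exponential model with zero nugget; fields
  with strong anisotropy or nugget effects will interpolate suboptimally
  (the IDW route is the fallback, not a tuned alternative).
- Scores are integers by design; sub-class gradients (e.g. within urban
  density) are not represented.
- Moran's I and Gi* assume complete, reasonably compact cell sets; highly
  fragmented masks thin the weights and weaken both statistics.
- Per-area uniformity within classes means province-scale statistics
  produce piecewise-constant surfaces; supply zone-wise totals for finer
  spatial contrast.
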