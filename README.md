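# hdindex

Quantifying human disturbance on gridded landscapes.

Landscape ecologists and environmental managers need a single, comparable
measure of how strongly people press on each square kilometer of a region —
through converting natural cover, consuming water and energy, and emitting
pollutants. `hdindex` implements the **Human Disturbances Index (HDI)**, a
cellwise composite of three component indices:

```
HDI = LNI + RCI + PEI          HDI ∈ [0, 60]
```

- **LNI** (land-use naturalness index, 0–10): each of nine land-use classes
  (arable, forest, grassland, artificial/natural water, urban, rural,
  industrial, unused) carries a naturalness score from the HAILS scheme —
  0 for untouched natural cover up to 10 for sealed settlement and industrial
  surfaces.
- **RCI** (resource consumption index, 0–20): water- and energy-consumption
  surfaces are built by spreading sectoral statistics over the land-use
  classes that generate them (agriculture → arable, industry → industrial,
  transport energy over urban/rural/industrial, residents via population
  density × per-capita rates), then each surface is standardized to 0–10 and
  the two scores summed.
- **PEI** (pollutant emission index, 0–30): coarse CO₂ and N₂O emission
  fields are upsampled to the analysis grid (ordinary kriging with a
  WLS-fitted exponential variogram, or IDW), a non-point pollution surface is
  confined to arable and rural land, and the three standardized scores are
  summed.

Standardization uses **Fisher–Jenks natural breaks** computed once on values
pooled across all periods (so scores are temporally comparable; exact zeros
score 0, Jenks classes map to 1–10). The HDI is classified into ten
equal-interval **disturbance levels** I–X (0–6, 7–12, …, 55–60), and
spatiotemporal pattern is summarized by the HDI-weighted **centroid
migration** track (displacement, compass bearing, speed), global **Moran's
I** (binary queen weights, normal or permutation inference), and
**Getis-Ord Gi\*** hot/cold spots (binary distance band including the self
term, categories at |Z| ≥ 1.645 / 1.960 / 2.576).

A seeded synthetic-landscape generator produces complete input bundles
(clustered land-use mosaics, population surfaces, sector statistics, coarse
emission fields with plantable ground-truth clusters), so the entire
pipeline is testable without any external data. Raster I/O uses the
plain-text ESRI ASCII grid format; zone polygons can be supplied as GeoJSON
and are rasterized on load. All inputs must share one projected CRS in
meters — the toolkit never reprojects.

## Worked example

```r
library(hdindex)

cfg <- scenarioConfig(seed = 42, nrow = 60, ncol = 60,
                      periods = c("1990", "1995", "2000"))
res <- runHdiPipeline(generateScenario(cfg), spatialStats = TRUE)

res$hdi[["2000"]]
#> HDIGrid (HDI = LNI + RCI + PEI)
#> GridSpec: 60 x 60 cells of 1000 m, origin (0, 60000), crs 'local-m'
#>   HDI range [4.00, 42.00], mean 25.79 over 3600 cells
```

Per-period shares of the disturbance levels (percent of cells; levels
VIII–X are empty in this scenario):

```r
res$shares[, c("period", levelLabels()[1:7])]
#>   period    I   II  III    IV    V   VI  VII
#> 1   1990 1.06 10.7 9.03  8.47 56.7 11.5 2.53
#> 2   1995 2.86 12.7 6.47 22.56 43.5 10.2 1.75
#> 3   2000 1.19 12.0 8.33  1.69 44.0 30.0 2.75
```

Most of this landscape sits at levels IV–VI — moderate disturbance driven by
the arable-dominated mosaic — with the level-VI share growing as sector
totals grow 5 %/period and urban land expands.

```r
trackSegments(res$track)
#>   from   to displacement bearing direction intervalYears speed
#> 1 1990 1995          888   187.1         S             5 177.6
#> 2 1995 2000         1248   315.3        NW             5 249.5
```

The disturbance-weighted centroid drifted 888 m south, then 1248 m
north-west at 249.5 m/year.

```r
m <- res$moran[["2000"]]
sprintf("Moran I = %.3f  Z = %.1f  p = %.3g", m$I, m$Z, m$p)
#> "Moran I = 0.522  Z = 61.9  p = 0"
table(res$hotspots[["2000"]]$category)
#>  cold90  cold95  cold99   hot90   hot95   hot99 not_significant
#>     119     187     554     157     309     503            1771
```

Disturbance is strongly spatially clustered (I = 0.52, far above the null
expectation −1/(n−1)), with coherent hot- and cold-spot regions.

A thin CLI over the same functions lives in `inst/scripts/hdi-toolkit.R`
(subcommands `simulate`, `lni`, `classify`, `tabulate`, `centroid`, `moran`,
`gistar`), reading and writing `.asc` rasters and CSV tables.

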