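#' Scenario configuration for the synthetic-landscape generator
#'
#' One seeded configuration fully determines a complete synthetic input
#' bundle: clustered categorical land-use mosaics per period, population
#' surfaces concentrated on settlement classes, sectoral consumption
#' statistics with a per-period trend, and coarse emission fields with
#' optional planted clusters for hot-spot ground truth.
#'
#' The default scenario mirrors a basin-scale study at toy scale: a 100 x 100
#' grid of 1 km cells, seven periods labeled 1990-2018 (so both the 5-year
#' and the trailing 3-year averaging conventions are exercised), an
#' arable-dominated class mix, and a mild multiplicative growth trend in
#' sector totals with a slow urbanization drift converting arable to urban
#' land between periods.
#'
#' @param seed integer seed; determines every generated output.
#' @param nrow,ncol,cellSize grid geometry (cellSize in meters).
#' @param periods character period labels, time-ordered.
#' @param classProportions named fractions over the nine classes, summing to
#'   1 (tolerance 1e-9).
#' @param clusteringStrength Gaussian smoothing radius (cells) of the latent
#'   field that is thresholded into classes; 0 gives a spatially random
#'   mosaic.
#' @param trend multiplicative per-period growth of sector totals (scalar or
#'   named per sector).
#' @param urbanDrift fraction of the landscape converted from arable to
#'   urban per period step.
#' @param urbanMean,ruralMean mean population density (persons/km^2) on
#'   urban / rural cells.
#' @param clusterPlants optional list of \code{list(x =, y =, radius =,
#'   effect =)} planted emission clusters (projected meters; effect in
#'   background-SD units).
#' @return a validated list of class \code{"scenarioConfig"}.
#' @export
scenarioConfig <- function(seed = 1L, nrow = 100L, ncol = 100L,
                           cellSize = 1000,
                           periods = c("1990", "1995", "2000", "2005",
                                       "2010", "2015", "2018"),
                           classProportions = c(
                             arable = 0.55, forest = 0.08, grassland = 0.06,
                             artificial_water = 0.02, natural_water = 0.04,
                             urban = 0.10, rural = 0.10, industrial = 0.03,
                             unused = 0.02),
                           clusteringStrength = 3,
                           trend = 1.05, urbanDrift = 0.003,
                           urbanMean = 2500, ruralMean = 400,
                           clusterPlants = NULL) {
  if (!setequal(names(classProportions), landUseClasses()))
    stop("config error: classProportions must cover exactly the nine classes")
  if (abs(sum(classProportions) - 1) > 1e-9)
    stop("config error: class proportions must sum to 1")
  if (any(classProportions < 0)) stop("config error: negative proportion")
  if (clusteringStrength < 0) stop("config error: negative clustering")
  structure(list(seed = as.integer(seed), nrow = as.integer(nrow),
                 ncol = as.integer(ncol), cellSize = cellSize,
                 periods = periods,
                 classProportions = classProportions[landUseClasses()],
                 clusteringStrength = clusteringStrength, trend = trend,
                 urbanDrift = urbanDrift, urbanMean = urbanMean,
                 ruralMean = ruralMean, clusterPlants = clusterPlants),
            class = "scenarioConfig")
}

.configSpec <- function(config)
  gridSpec(config$nrow, config$ncol, config$cellSize)

#' Generate a clustered categorical land-use mosaic
#'
#' Thresholds a seeded Gaussian-smoothed noise field at the cumulative
#' class-proportion quantiles: ranks of the latent field are split so class
#' shares match the configured proportions to within one cell, while spatial
#' clustering grows with \code{clusteringStrength}.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param period optional period label; later periods shift
#'   \code{urbanDrift} of the landscape from arable to urban.
#' @return A \linkS4class{LandUseGrid}.
#' @export
generateLandUse <- function(config, period = NULL) {
  spec <- .configSpec(config)
  step <- if (is.null(period)) 0L else match(period, config$periods) - 1L
  if (is.null(step) || is.na(step)) stop("unknown period label")
  props <- config$classProportions
  shift <- min(config$urbanDrift * step, props["arable"])
  props["arable"] <- props["arable"] - shift
  props["urban"] <- props["urban"] + shift
  field <- withSeed(config$seed + 1000L, {
    .smoothField(matrix(stats::runif(spec@nrow * spec@ncol),
                        spec@nrow, spec@ncol),
                 config$clusteringStrength)
  })
  n <- length(field)
  rk <- rank(field, ties.method = "first")
  cum <- cumsum(props)
  codes <- matrix(findInterval((rk - 0.5) / n, cum) + 1L,
                  spec@nrow, spec@ncol)
  codes[codes > 9L] <- 9L
  landUseGrid(codes, spec = spec)
}

#' Generate a population-density surface
#'
#' Lognormal densities on settlement cells with configured urban and rural
#' means (urban typically an order of magnitude above rural), exactly 0 on
#' every other class.
#'
#' @param landUse a \linkS4class{LandUseGrid}.
#' @param config a \code{\link{scenarioConfig}}.
#' @return A \linkS4class{ValueGrid} (persons/km^2).
#' @export
generatePopulation <- function(landUse, config) {
  v <- matrix(0, landUse@spec@nrow, landUse@spec@ncol)
  v[is.na(landUse@codes)] <- NA
  u <- classMask(landUse, "urban"); r <- classMask(landUse, "rural")
  withSeed(config$seed + 2000L, {
    sdlog <- 0.3
    v[u] <- config$urbanMean * exp(stats::rnorm(sum(u), -sdlog^2 / 2, sdlog))
    v[r] <- config$ruralMean * exp(stats::rnorm(sum(r), -sdlog^2 / 2, sdlog))
  })
  valueGrid(v, spec = landUse@spec, units = "persons/km2")
}

# Baseline sector totals for the first period; chosen at basin scale
# (~1e5 km2) so densities land in realistic ranges.
.baseTotals <- function(resource) {
  if (resource == "water")
    c(agriculture = 220, industry = 60, urban_public = 25,
      forestry_husbandry = 12, urban_residents = 20, rural_residents = 15)
  else
    c(industry = 6500, agriculture = 900, urban_public = 1100,
      transport = 1400, urban_residents = 1600, rural_residents = 800)
}

#' Generate sectoral consumption statistics
#'
#' Per-period sector totals following the configured multiplicative trend
#' (quantity_t = quantity_1 * trend^(t-1)), with small seeded lognormal
#' noise. Water totals are in 1e8 m^3, energy totals in 1e4 tce.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param resource \code{"water"} or \code{"energy"}.
#' @param noiseSd lognormal sd of the per-record noise (0 for exact trend).
#' @return data.frame: period, region, sector, quantity, units.
#' @export
generateStatistics <- function(config, resource = c("water", "energy"),
                               noiseSd = 0.05) {
  resource <- match.arg(resource)
  base <- .baseTotals(resource)
  trend <- config$trend
  if (length(trend) == 1L && is.null(names(trend)))
    trend <- stats::setNames(rep(trend, length(base)), names(base))
  rows <- withSeed(config$seed + if (resource == "water") 3000L else 3500L, {
    do.call(rbind, lapply(seq_along(config$periods), function(t) {
      noise <- if (noiseSd > 0)
        exp(stats::rnorm(length(base), -noiseSd^2 / 2, noiseSd)) else 1
      data.frame(period = config$periods[t], region = "basin",
                 sector = names(base),
                 quantity = as.numeric(base * trend[names(base)]^(t - 1) *
                                         noise),
                 units = if (resource == "water") "1e8 m3" else "1e4 tce",
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(rows) <- NULL
  rows
}

#' Plant high-value clusters into a grid
#'
#' Adds \code{effect * sd(values)} inside each disc-shaped cluster and
#' returns the modified grid together with the ground-truth cluster mask.
#'
#' @param grid a \linkS4class{ValueGrid}.
#' @param plants list of \code{list(x =, y =, radius =, effect =)} in
#'   projected meters / background-SD units.
#' @return list: \code{grid} (modified), \code{mask} (logical matrix).
#' @export
plantClusters <- function(grid, plants) {
  v <- grid@values
  s <- stats::sd(v, na.rm = TRUE)
  cc <- cellCenters(grid@spec)
  mask <- matrix(FALSE, nrow(v), ncol(v))
  for (p in plants) {
    inside <- (cc$x - p$x)^2 + (cc$y - p$y)^2 <= p$radius^2
    v[inside] <- v[inside] + p$effect * s
    mask <- mask | inside
  }
  list(grid = valueGrid(v, spec = grid@spec, units = grid@units),
       mask = mask)
}

#' Generate a coarse emission field
#'
#' A smooth non-negative lognormal field on a coarse grid at 4x the scenario
#' cell size (emulating a coarse global emission inventory), with any
#' configured clusters planted on top. The ground-truth cluster mask (on the
#' coarse grid) is returned alongside.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param pollutant \code{"CO2"} or \code{"N2O"}; each pollutant and period
#'   gets an independent seeded draw.
#' @param period optional period label (shifts the seed).
#' @return list: \code{field} (\linkS4class{EmissionField}), \code{grid}
#'   (coarse \linkS4class{ValueGrid}), \code{mask} (logical matrix of
#'   planted-cluster cells).
#' @export
generateEmissionField <- function(config, pollutant = "CO2", period = NULL) {
  spec <- .configSpec(config)
  coarse <- gridSpec(ceiling(spec@nrow / 4), ceiling(spec@ncol / 4),
                     spec@cellSize * 4, originX = spec@originX,
                     originY = spec@originY, crs = spec@crs)
  step <- if (is.null(period)) 0L else match(period, config$periods) - 1L
  if (is.na(step)) stop("unknown period label")
  seed <- config$seed + 4000L + step * 10L +
    if (pollutant == "CO2") 0L else 1L
  base <- withSeed(seed, {
    z <- .smoothField(matrix(stats::rnorm(coarse@nrow * coarse@ncol),
                             coarse@nrow, coarse@ncol), 2)
    100 * exp(z / max(stats::sd(z), 1e-12) * 0.4)
  })
  g <- valueGrid(base, spec = coarse, units = "kt/cell")
  mask <- matrix(FALSE, coarse@nrow, coarse@ncol)
  if (!is.null(config$clusterPlants)) {
    pl <- plantClusters(g, config$clusterPlants)
    g <- pl$grid; mask <- pl$mask
  }
  list(field = asEmissionField(g, pollutant), grid = g, mask = mask)
}

#' Generate a complete synthetic input bundle
#'
#' Everything the pipeline needs for every period: land use, population,
#' water and energy statistics, coarse CO2 and N2O emission fields, and the
#' per-capita rate constants.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return list: spec, periods, landUse (list), population (list),
#'   waterStats, energyStats, co2, n2o (lists of EmissionField results),
#'   rates (waterRates, energyRates, nonpoint).
#' @export
generateScenario <- function(config) {
  periods <- config$periods
  landUse <- lapply(periods, function(p) generateLandUse(config, p))
  names(landUse) <- periods
  population <- lapply(landUse, function(lu) generatePopulation(lu, config))
  list(spec = .configSpec(config), periods = periods, landUse = landUse,
       population = population,
       waterStats = generateStatistics(config, "water"),
       energyStats = generateStatistics(config, "energy"),
       co2 = stats::setNames(lapply(periods, function(p)
         generateEmissionField(config, "CO2", p)), periods),
       n2o = stats::setNames(lapply(periods, function(p)
         generateEmissionField(config, "N2O", p)), periods),
       rates = list(
         # per-capita rates in the statistics' units per person per year
         waterRates = list(urban = 70 / 1e8, rural = 40 / 1e8),
         energyRates = list(urban = 0.9e-4, rural = 0.4e-4),
         nonpoint = list(perCapitaRural = 0.012, fertilizerUseRate = 0.35,
                         arableApplicationRate = 22)))
}
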