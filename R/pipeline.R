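#' Run the full disturbance-index pipeline on an input bundle
#'
#' From raw inputs to classified disturbance maps and spatiotemporal
#' analytics, for every period:
#' \enumerate{
#'   \item LNI: naturalness scores assigned per land-use class (already on
#'     the 0-10 scale, no standardization).
#'   \item RCI: water and energy consumption surfaces built from sectoral
#'     statistics, population and per-capita rates; each variable
#'     standardized to 0-10 with breaks pooled across all periods; the two
#'     scores summed (0-20).
#'   \item PEI: coarse CO2 and N2O fields interpolated to the analysis grid,
#'     plus the non-point surface on arable/rural land; each standardized as
#'     above and summed (0-30).
#'   \item HDI = LNI + RCI + PEI, classified into levels I..X, level shares
#'     tabulated, and the HDI-weighted centroid tracked across periods.
#' }
#'
#' @param bundle a bundle from \code{\link{generateScenario}} (or an
#'   equivalently shaped list of real inputs).
#' @param interpMethod interpolation for the coarse emission fields
#'   (\code{"idw"} or \code{"ordinary_kriging"}).
#' @param k score classes for standardization.
#' @param spatialStats also compute Moran's I (queen weights, normality z)
#'   and Gi* hot spots per period.
#' @param gistarBand Gi* band distance (default 2 cells).
#' @return list with per-period \code{hdi} (HDIGrids), \code{levels}
#'   (LevelGrids), \code{shares} (level-share table across periods),
#'   \code{track} (\linkS4class{CentroidTrack}), \code{breaks} (the pooled
#'   BreaksSpec per variable), and, if requested, \code{moran} and
#'   \code{hotspots} per period.
#' @export
runHdiPipeline <- function(bundle, interpMethod = c("idw",
                                                    "ordinary_kriging"),
                           k = 10L, spatialStats = FALSE,
                           gistarBand = NULL) {
  interpMethod <- match.arg(interpMethod)
  spec <- bundle$spec
  periods <- bundle$periods
  rates <- bundle$rates

  lni <- lapply(periods, function(p)
    assignNaturalness(bundle$landUse[[p]]))
  names(lni) <- periods

  water <- lapply(periods, function(p)
    buildConsumptionSurface(bundle$waterStats, p, bundle$landUse[[p]],
                            bundle$population[[p]], rates$waterRates,
                            units = "1e8 m3/km2"))
  energy <- lapply(periods, function(p)
    buildConsumptionSurface(bundle$energyStats, p, bundle$landUse[[p]],
                            bundle$population[[p]], rates$energyRates,
                            units = "1e4 tce/km2"))
  waterStd <- standardizeScores(water, k = k)
  energyStd <- standardizeScores(energy, k = k)
  rci <- lapply(periods, function(p) {
    i <- match(p, periods)
    sumLayers(list(waterStd$scores[[i]], energyStd$scores[[i]]))
  })
  names(rci) <- periods

  co2 <- lapply(periods, function(p)
    interpolateToGrid(bundle$co2[[p]]$field, spec, method = interpMethod))
  n2o <- lapply(periods, function(p)
    interpolateToGrid(bundle$n2o[[p]]$field, spec, method = interpMethod))
  nonpoint <- lapply(periods, function(p)
    landCoverIndicator(nonpointEmissionSurface(bundle$landUse[[p]],
                                               bundle$population[[p]],
                                               rates$nonpoint)))
  co2Std <- standardizeScores(co2, k = k)
  n2oStd <- standardizeScores(n2o, k = k)
  npStd <- standardizeScores(nonpoint, k = k)
  pei <- lapply(periods, function(p) {
    i <- match(p, periods)
    sumLayers(list(co2Std$scores[[i]], n2oStd$scores[[i]],
                   npStd$scores[[i]]))
  })
  names(pei) <- periods

  hdi <- lapply(periods, function(p)
    combineHdi(lni[[p]], rci[[p]], pei[[p]]))
  names(hdi) <- periods
  levels <- lapply(hdi, classifyLevels)
  shares <- do.call(rbind, lapply(periods, function(p)
    tabulateLevels(levels[[p]], period = p)))

  cents <- do.call(rbind, lapply(periods, function(p) {
    xy <- weightedCentroid(hdi[[p]])
    data.frame(period = p, X = xy["X"], Y = xy["Y"],
               stringsAsFactors = FALSE)
  }))
  rownames(cents) <- NULL
  yrs <- suppressWarnings(as.numeric(periods))
  intervals <- if (!anyNA(yrs)) diff(yrs) else rep(1, length(periods) - 1L)
  track <- if (length(periods) >= 2L) centroidTrack(cents, intervals)
           else NULL

  out <- list(periods = periods, lni = lni, rci = rci, pei = pei,
              hdi = hdi, levels = levels, shares = shares, track = track,
              breaks = list(water = waterStd$breaks,
                            energy = energyStd$breaks,
                            co2 = co2Std$breaks, n2o = n2oStd$breaks,
                            nonpoint = npStd$breaks))
  if (spatialStats) {
    w <- buildWeights(spec, !is.na(hdi[[1]]@hdi), scheme = "queen")
    out$moran <- lapply(hdi, function(h) moranZ(h, w))
    out$hotspots <- lapply(hdi, function(h)
      getisOrdGiStar(h, d = gistarBand))
  }
  out
}
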