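#' Default standard-coal-equivalent conversion factors
#'
#' Conversion factors to tonnes of standard coal equivalent (tce) per native
#' unit, following the Chinese national General Rules for Calculation of
#' Comprehensive Energy Consumption conventions. These are inputs, not
#' constants of the method: supply your own table for other conventions.
#'
#' Units per carrier: raw_coal, coke, crude_oil, gasoline, kerosene, diesel,
#' fuel_oil in tce per tonne; natural_gas in tce per 1000 m3; electricity in
#' tce per MWh.
#'
#' @return named numeric vector of positive factors.
#' @export
defaultFuelConversionTable <- function() {
  c(raw_coal = 0.7143, coke = 0.9714, crude_oil = 1.4286,
    gasoline = 1.4714, kerosene = 1.4714, diesel = 1.4571,
    fuel_oil = 1.4286, natural_gas = 1.3300, electricity = 0.1229)
}

#' Convert carrier amounts to standard coal equivalent
#'
#' Linear conversion: returns sum(amount * factor) over carriers, in tce.
#'
#' @param quantities named numeric vector of non-negative amounts, names are
#'   energy carriers.
#' @param table named numeric conversion table (tce per native unit), see
#'   \code{\link{defaultFuelConversionTable}}.
#' @return numeric scalar, tce.
#' @examples
#' toStandardCoal(c(raw_coal = 100, electricity = 50))
#' @export
toStandardCoal <- function(quantities, table = defaultFuelConversionTable()) {
  if (length(quantities) == 0L) return(0)
  if (any(table <= 0)) stop("conversion factors must be positive")
  unknown <- setdiff(names(quantities), names(table))
  if (length(unknown))
    stop("conversion error: unknown carrier(s): ",
         paste(unknown, collapse = ", "))
  sum(quantities * table[names(quantities)])
}

#' Average a yearly series over an explicit year window
#'
#' Arithmetic mean over exactly the window years. The study convention is
#' 5-year blocks, with 2016-2018 averaged as a 3-year block; windows are
#' explicit year sets, so both are expressed the same way.
#'
#' @param series data.frame with columns \code{year} and \code{value}, or a
#'   numeric vector named by year.
#' @param window integer vector of years that must all be present.
#' @return numeric scalar.
#' @examples
#' temporalAverage(data.frame(year = 2016:2018, value = c(1, 2, 3)), 2016:2018)
#' @export
temporalAverage <- function(series, window) {
  if (is.data.frame(series)) {
    years <- series$year; vals <- series$value
  } else {
    years <- as.integer(names(series)); vals <- as.numeric(series)
  }
  miss <- setdiff(as.integer(window), years)
  if (length(miss))
    stop("coverage error: missing year(s) in series: ",
         paste(sort(miss), collapse = ", "))
  mean(vals[match(as.integer(window), years)])
}

#' Allocate a sectoral total over land-use classes as a per-area density
#'
#' Spreads \code{total} over the cells of the target classes and returns a
#' density surface (quantity per km^2 per cell). With
#' \code{split = "proportional_area"} the density is uniform across all
#' target cells (each class receives a share proportional to its area). With
#' explicit fractions, each class receives \code{total * fraction} spread
#' uniformly over its own cells. Non-target cells are 0 (nodata cells of the
#' land-use grid stay nodata). The surface integrates back to \code{total}:
#' sum over cells times cell area equals \code{total} to 1e-9 relative.
#'
#' @param total non-negative sectoral total (quantity units).
#' @param landUse a \linkS4class{LandUseGrid}.
#' @param targetClasses character vector of receiving classes.
#' @param split \code{"proportional_area"} or a named numeric vector of
#'   fractions over \code{targetClasses} summing to 1.
#' @param units unit label for the output density surface.
#' @return A \linkS4class{ValueGrid} of densities (quantity / km^2).
#' @export
allocatePerArea <- function(total, landUse, targetClasses,
                            split = "proportional_area", units = "") {
  stopifnot(is(landUse, "LandUseGrid"), total >= 0)
  cellArea <- cellAreaKm2(landUse@spec)
  v <- matrix(0, nrow(landUse@codes), ncol(landUse@codes))
  v[is.na(landUse@codes)] <- NA
  masks <- lapply(targetClasses, function(cl) classMask(landUse, cl))
  counts <- vapply(masks, sum, 0L)
  if (sum(counts) == 0L)
    stop("allocation error: no cells of target class(es) ",
         paste(targetClasses, collapse = ", "))
  if (identical(split, "proportional_area")) {
    dens <- total / (sum(counts) * cellArea)
    for (m in masks) v[m] <- dens
  } else {
    if (is.null(names(split)) || !setequal(names(split), targetClasses))
      stop("explicit split fractions must be named by the target classes")
    if (abs(sum(split) - 1) > 1e-9)
      stop("explicit split fractions must sum to 1")
    for (i in seq_along(targetClasses)) {
      frac <- split[[targetClasses[i]]]
      if (frac == 0) next
      if (counts[i] == 0L)
        stop("allocation error: no cells of class ", targetClasses[i],
             " to receive fraction ", frac)
      v[masks[[i]]] <- total * frac / (counts[i] * cellArea)
    }
  }
  valueGrid(v, spec = landUse@spec, units = units)
}

#' Residential consumption surface from population density
#'
#' Urban cells receive density * urban rate, rural cells density * rural
#' rate, every other class 0. Rates are per-person-per-year quantities, so
#' with population in persons/km^2 the output is quantity per km^2 per year.
#'
#' @param population aligned \linkS4class{ValueGrid}, persons/km^2.
#' @param landUse aligned \linkS4class{LandUseGrid}.
#' @param rates list or named vector with elements \code{urban} and
#'   \code{rural}, per-capita rates (quantity / person / year), both >= 0.
#' @param units unit label for the output.
#' @return A \linkS4class{ValueGrid}.
#' @export
residentialConsumption <- function(population, landUse, rates, units = "") {
  .stopifNotAligned(population, landUse)
  if (any(population@values < 0, na.rm = TRUE))
    stop("input error: negative population density")
  rates <- as.list(rates)
  if (is.null(rates$urban) || is.null(rates$rural) ||
      rates$urban < 0 || rates$rural < 0)
    stop("rates must provide non-negative 'urban' and 'rural'")
  v <- matrix(0, nrow(population@values), ncol(population@values))
  v[is.na(landUse@codes) | is.na(population@values)] <- NA
  u <- classMask(landUse, "urban") & !is.na(population@values)
  r <- classMask(landUse, "rural") & !is.na(population@values)
  v[u] <- population@values[u] * rates$urban
  v[r] <- population@values[r] * rates$rural
  valueGrid(v, spec = population@spec, units = units)
}

#' Spread transport energy over built-up classes
#'
#' Transport energy use is not confined to roadways, so the sectoral total is
#' allocated uniformly per unit area over urban, rural and industrial land.
#'
#' @param total transport energy total (tce).
#' @param landUse a \linkS4class{LandUseGrid}.
#' @return A \linkS4class{ValueGrid} of tce/km^2.
#' @export
transportEnergySpread <- function(total, landUse) {
  allocatePerArea(total, landUse, c("urban", "rural", "industrial"),
                  units = "tce/km2")
}

#' Default sector-to-class allocation map
#'
#' How sectoral totals are spatialized: agriculture onto arable land,
#' industry onto industrial land, urban public services onto urban land,
#' forestry and husbandry onto forest and grassland (proportional to area),
#' transport onto urban/rural/industrial land, and the two resident sectors
#' by population and per-capita rates rather than by area. Sectors mapped to
#' \code{"ignore"} are skipped with a message, never silently dropped.
#'
#' @return named list: each element a character vector of target classes, or
#'   \code{"population"} / \code{"ignore"}.
#' @export
defaultSectorMap <- function() {
  list(agriculture = "arable",
       industry = "industrial",
       urban_public = "urban",
       forestry_husbandry = c("forest", "grassland"),
       transport = c("urban", "rural", "industrial"),
       urban_residents = "population",
       rural_residents = "population",
       other = "ignore")
}

#' Build a consumption surface for one period
#'
#' Sums the per-area allocations of every mapped sector plus the
#' population-based residential component into one density surface
#' (quantity/km^2) for the given period. Region totals are summed across
#' regions unless a zone raster is supplied, in which case allocation is
#' performed region by region within its zone and the results mosaicked.
#'
#' Sector handling is driven by \code{sectorMap}: class vectors are allocated
#' with \code{\link{allocatePerArea}} (proportional to area across the listed
#' classes), \code{"population"} sectors are covered by the per-capita
#' residential component (their table totals are not re-allocated), and
#' \code{"ignore"} sectors are skipped with a message. A sector present in
#' the statistics but absent from the map is an error.
#'
#' @param stats data.frame with columns \code{period}, \code{region},
#'   \code{sector}, \code{quantity} (and optionally \code{units}).
#' @param period the period label to build.
#' @param landUse a \linkS4class{LandUseGrid}.
#' @param population aligned \linkS4class{ValueGrid}, persons/km^2; required
#'   unless no sector maps to \code{"population"} and rates are NULL.
#' @param rates per-capita rates for \code{\link{residentialConsumption}}, or
#'   NULL to omit the residential component.
#' @param sectorMap see \code{\link{defaultSectorMap}}.
#' @param zones optional aligned zone raster; zone ids must be supplied as
#'   \code{regionZones}, a named vector mapping region labels to zone ids.
#' @param regionZones see \code{zones}.
#' @param units unit label of the output surface.
#' @return A \linkS4class{ValueGrid} density surface.
#' @export
buildConsumptionSurface <- function(stats, period, landUse,
                                    population = NULL, rates = NULL,
                                    sectorMap = defaultSectorMap(),
                                    zones = NULL, regionZones = NULL,
                                    units = "") {
  need <- c("period", "region", "sector", "quantity")
  if (!all(need %in% names(stats)))
    stop("statistics table must have columns ",
         paste(need, collapse = ", "))
  if (any(stats$quantity < 0)) stop("quantities must be non-negative")
  if (anyDuplicated(stats[c("period", "region", "sector")]))
    stop("(period, region, sector) must be unique in the statistics table")
  rows <- stats[stats$period == period, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no statistics for period ", period)
  unmapped <- setdiff(unique(rows$sector), names(sectorMap))
  if (length(unmapped))
    stop("sector(s) not in sector map (map or explicitly ignore them): ",
         paste(unmapped, collapse = ", "))
  spec <- landUse@spec
  acc <- matrix(0, spec@nrow, spec@ncol)
  acc[is.na(landUse@codes)] <- NA

  allocateRegion <- function(lu, sectorTotals) {
    out <- matrix(0, spec@nrow, spec@ncol)
    for (sec in names(sectorTotals)) {
      target <- sectorMap[[sec]]
      if (identical(target, "ignore")) {
        message("sector '", sec, "' is mapped to ignore; total ",
                sectorTotals[[sec]], " not allocated")
        next
      }
      if (identical(target, "population")) next  # handled via rates
      g <- allocatePerArea(sectorTotals[[sec]], lu, target)
      out <- out + ifelse(is.na(g@values), 0, g@values)
    }
    out
  }

  if (is.null(zones)) {
    totals <- tapply(rows$quantity, rows$sector, sum)
    acc <- acc + allocateRegion(landUse, as.list(totals))
  } else {
    if (is.null(regionZones))
      stop("zone-wise allocation needs 'regionZones' mapping regions to ids")
    .stopifNotAligned(landUse, zones)
    zm <- if (is(zones, "LandUseGrid")) zones@codes else zones@values
    for (reg in unique(rows$region)) {
      zid <- regionZones[[reg]]
      if (is.null(zid)) stop("region '", reg, "' has no zone id")
      inZone <- !is.na(zm) & zm == zid
      if (!any(inZone)) stop("empty-zone error: region '", reg, "'")
      codes <- landUse@codes
      codes[!inZone] <- NA
      luz <- landUseGrid(codes, spec = spec, legend = landUse@legend)
      rr <- rows[rows$region == reg, ]
      acc <- acc + allocateRegion(luz, stats::setNames(as.list(rr$quantity),
                                                       rr$sector))
    }
  }

  if (!is.null(rates)) {
    if (is.null(population))
      stop("population grid required for residential rates")
    res <- residentialConsumption(population, landUse, rates)
    acc <- acc + res@values
  }
  valueGrid(acc, spec = spec, units = units)
}
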