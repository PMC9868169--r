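#' Standardize surfaces to 0-10 disturbance scores
#'
#' Converts one variable's per-period surfaces to integer contribution scores
#' on a common scale. Natural-breaks classes are computed ONCE on the
#' non-nodata, nonzero values pooled across all periods, so the same raw
#' value always maps to the same score in every period and scores are
#' temporally comparable. Exact-zero cells (no activity) score 0; nonzero
#' cells receive their Jenks class label 1..k. If the pooled nonzero values
#' have fewer than \code{k} distinct values the standardization falls back to
#' equal-interval breaks over the pooled range with a warning.
#'
#' @param surfaces a \linkS4class{ValueGrid} or list of aligned ValueGrids
#'   (one per period, same variable).
#' @param k number of score classes (default 10).
#' @param breaks optionally, a precomputed \linkS4class{BreaksSpec} (e.g.
#'   read back from a JSON sidecar) to apply instead of pooling.
#' @param nbins quantile-bin count passed to \code{\link{jenksBreaks}}.
#' @return list with \code{scores} (list of score ValueGrids, same length and
#'   order as the input) and \code{breaks} (the \linkS4class{BreaksSpec}
#'   used).
#' @export
standardizeScores <- function(surfaces, k = 10L, breaks = NULL,
                              nbins = 2048L) {
  single <- !is.list(surfaces)
  if (single) surfaces <- list(surfaces)
  do.call(.stopifNotAligned, surfaces)
  pooled <- unlist(lapply(surfaces, function(g) g@values))
  pooled <- pooled[!is.na(pooled) & pooled != 0]
  if (is.null(breaks)) {
    if (length(pooled) == 0L) {
      breaks <- NULL  # all-zero surfaces: all scores 0, no breaks needed
    } else if (length(unique(pooled)) < k) {
      warning("fewer than k distinct pooled values; ",
              "falling back to equal-interval standardization")
      breaks <- equalIntervalBreaks(pooled, k)
    } else {
      breaks <- jenksBreaks(pooled, k, nbins = nbins)
    }
  }
  scores <- lapply(surfaces, function(g) {
    v <- g@values
    out <- matrix(NA_real_, nrow(v), ncol(v))
    zero <- !is.na(v) & v == 0
    nz <- !is.na(v) & v != 0
    out[zero] <- 0
    if (any(nz)) out[nz] <- as.numeric(classifyByBreaks(v[nz], breaks))
    valueGrid(out, spec = g@spec, units = "score")
  })
  list(scores = if (single) scores[[1]] else scores, breaks = breaks)
}

#' Weighted cellwise sum of score layers
#'
#' @param layers list of aligned \linkS4class{ValueGrid}s.
#' @param weights numeric weights, one per layer (default all 1).
#' @return A \linkS4class{ValueGrid}; nodata propagates.
#' @export
sumLayers <- function(layers, weights = rep(1, length(layers))) {
  stopifnot(length(layers) >= 1L)
  if (length(weights) != length(layers))
    stop("weights length must match the number of layers")
  do.call(.stopifNotAligned, layers)
  acc <- layers[[1]]@values * weights[1]
  for (i in seq_along(layers)[-1]) acc <- acc + layers[[i]]@values * weights[i]
  valueGrid(acc, spec = layers[[1]]@spec, units = "score")
}

#' Combine component indices into the HDI
#'
#' HDI = LNI + RCI + PEI cellwise. Component ranges are validated: LNI in
#' [0, 10] (one scored dataset), RCI in [0, 20] (water + energy), PEI in
#' [0, 30] (CO2 + N2O + non-point), so HDI lies in [0, 60].
#'
#' @param lni,rci,pei aligned \linkS4class{ValueGrid} score layers.
#' @return An \linkS4class{HDIGrid}.
#' @export
combineHdi <- function(lni, rci, pei) {
  .stopifNotAligned(lni, rci, pei)
  caps <- c(lni = 10, rci = 20, pei = 30)
  layers <- list(lni = lni, rci = rci, pei = pei)
  for (nm in names(layers)) {
    v <- layers[[nm]]@values
    if (any(v < -1e-9 | v > caps[nm] + 1e-9, na.rm = TRUE))
      stop("range error: ", nm, " outside [0, ", caps[nm], "]")
  }
  hdi <- lni@values + rci@values + pei@values
  new("HDIGrid", spec = lni@spec, hdi = hdi, lni = lni@values,
      rci = rci@values, pei = pei@values)
}

#' Classify HDI into ten equal-interval disturbance levels
#'
#' Level I covers HDI in [0, 6]; level n > 1 covers the half-open bin
#' (6(n-1), 6n], i.e. n = ceiling(HDI / 6). On integer HDI values this
#' reproduces the standard level table 0-6 (I), 7-12 (II), ..., 55-60 (X).
#'
#' @param hdi an \linkS4class{HDIGrid}, or a \linkS4class{ValueGrid} of HDI
#'   values in [0, 60].
#' @return A \linkS4class{LevelGrid}.
#' @export
classifyLevels <- function(hdi) {
  v <- if (is(hdi, "HDIGrid")) hdi@hdi else hdi@values
  spec <- gridSpecOf(hdi)
  if (any(v < -1e-9 | v > 60 + 1e-9, na.rm = TRUE))
    stop("range error: HDI outside [0, 60]")
  lev <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  lev[ok] <- pmin(pmax(as.integer(ceiling(v[ok] / 6)), 1L), 10L)
  new("LevelGrid", spec = spec, levels = lev)
}

#' Roman labels of the ten disturbance levels
#' @return character vector "I".."X".
#' @export
levelLabels <- function() as.character(utils::as.roman(1:10))

#' Tabulate level shares by zone and period
#'
#' Per zone (or the whole grid), the percentage of non-nodata cells falling
#' in each of the ten levels. Percentages sum to 100 per zone exactly before
#' rounding; \code{round2 = TRUE} emulates a published two-decimal table.
#' Empty zones are omitted with a warning.
#'
#' @param levels a \linkS4class{LevelGrid}.
#' @param zones optional aligned integer zone raster.
#' @param period period label written into the output.
#' @param round2 round percentages to 2 decimals.
#' @return data.frame: zone, period, then columns I..X of percentages.
#' @export
tabulateLevels <- function(levels, zones = NULL, period = "", round2 = FALSE) {
  lv <- levels@levels
  zoneIds <- "all"
  zm <- NULL
  if (!is.null(zones)) {
    .stopifNotAligned(levels, zones)
    zm <- if (is(zones, "LandUseGrid")) zones@codes else zones@values
    zoneIds <- sort(unique(zm[!is.na(zm)]))
  }
  rows <- lapply(zoneIds, function(z) {
    sel <- if (is.null(zm)) !is.na(lv) else !is.na(lv) & !is.na(zm) & zm == z
    n <- sum(sel)
    if (n == 0L) {
      warning("zone ", z, " has no classified cells; omitted")
      return(NULL)
    }
    cnt <- tabulate(lv[sel], nbins = 10L)
    pct <- 100 * cnt / n
    if (round2) pct <- round(pct, 2)
    out <- data.frame(zone = as.character(z), period = period,
                      stringsAsFactors = FALSE)
    out[levelLabels()] <- as.list(pct)
    out
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
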