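#' @import methods
#' @importFrom stats optim pnorm quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

#' Canonical land-use classes
#'
#' The nine land-use classes of the disturbance framework, in canonical order,
#' plus the reserved \code{"nodata"} label. All legends, naturalness tables and
#' sector maps refer to these names.
#'
#' @return Character vector of the nine class names.
#' @export
landUseClasses <- function() {
  c("arable", "forest", "grassland", "artificial_water", "natural_water",
    "urban", "rural", "industrial", "unused")
}

#' GridSpec: georeferencing of a regular raster grid
#'
#' Describes a regular grid in a projected coordinate system with units of
#' meters. \code{originX}/\code{originY} are the coordinates of the outer
#' (north-west) corner of the top-left cell; row index increases southward.
#' Cell \eqn{(i, j)} (0-based) has center
#' \eqn{x = originX + (j + 0.5) \cdot cellSize},
#' \eqn{y = originY - (i + 0.5) \cdot cellSize}.
#' Two grids are aligned iff all five geometry fields and the CRS label agree.
#' The CRS label is opaque: no reprojection is ever attempted, and distances
#' are meaningful only because inputs are required to be in one projected CRS
#' in meters.
#'
#' @slot nrow,ncol positive integers, grid dimensions.
#' @slot cellSize cell edge length in meters.
#' @slot originX,originY projected coordinates (m) of the NW corner.
#' @slot crs opaque CRS label.
#' @export
setClass("GridSpec",
  representation(nrow = "integer", ncol = "integer", cellSize = "numeric",
                 originX = "numeric", originY = "numeric", crs = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@nrow) != 1L || is.na(object@nrow) || object@nrow < 1L)
      msg <- c(msg, "nrow must be a single integer >= 1")
    if (length(object@ncol) != 1L || is.na(object@ncol) || object@ncol < 1L)
      msg <- c(msg, "ncol must be a single integer >= 1")
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (!is.finite(object@originX) || !is.finite(object@originY))
      msg <- c(msg, "origin coordinates must be finite")
    if (length(object@crs) != 1L || is.na(object@crs))
      msg <- c(msg, "crs must be a single string")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a GridSpec
#'
#' @param nrow,ncol grid dimensions.
#' @param cellSize cell edge length in meters.
#' @param originX,originY projected coordinates (m) of the north-west corner
#'   of the top-left cell.
#' @param crs opaque CRS label (default \code{"local-m"}).
#' @return A \linkS4class{GridSpec}.
#' @examples
#' gridSpec(10, 10, 1000)
#' @export
gridSpec <- function(nrow, ncol, cellSize, originX = 0, originY = nrow * cellSize,
                     crs = "local-m") {
  new("GridSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      cellSize = as.numeric(cellSize), originX = as.numeric(originX),
      originY = as.numeric(originY), crs = as.character(crs))
}

#' ValueGrid: continuous raster surface
#'
#' A real-valued raster on a \linkS4class{GridSpec}. Nodata cells are stored
#' as \code{NA} and propagate through all arithmetic. A score grid is a
#' ValueGrid whose values are confined to [0, 10] (or [0, 60] for a combined
#' index); no separate class is used.
#'
#' @slot spec the \linkS4class{GridSpec}.
#' @slot values numeric matrix (nrow x ncol), \code{NA} = nodata.
#' @slot units free-text unit label.
#' @export
setClass("ValueGrid",
  representation(spec = "GridSpec", values = "matrix", units = "character"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be a numeric matrix")
    if (!identical(dim(object@values),
                   c(object@spec@nrow, object@spec@ncol)))
      msg <- c(msg, "values dimensions must match the GridSpec")
    if (any(is.infinite(object@values)))
      msg <- c(msg, "values must be finite wherever not nodata")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ValueGrid
#'
#' @param values numeric matrix, \code{NA} for nodata.
#' @param spec a \linkS4class{GridSpec}; defaults to a unit-origin spec
#'   matching the matrix dimensions with 1 km cells.
#' @param units free-text unit label.
#' @return A \linkS4class{ValueGrid}.
#' @export
valueGrid <- function(values, spec = NULL, units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(spec)) spec <- gridSpec(nrow(values), ncol(values), 1000)
  new("ValueGrid", spec = spec, values = values, units = as.character(units))
}

#' LandUseGrid: categorical land-use raster
#'
#' Integer-coded categorical raster with a legend mapping codes to the nine
#' canonical land-use classes (see \code{\link{landUseClasses}}). \code{NA}
#' codes are nodata and are excluded from all statistics.
#'
#' @slot spec the \linkS4class{GridSpec}.
#' @slot codes integer matrix, \code{NA} = nodata.
#' @slot legend named integer vector: names are class labels, values codes.
#' @export
setClass("LandUseGrid",
  representation(spec = "GridSpec", codes = "matrix", legend = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!is.integer(object@codes))
      msg <- c(msg, "codes must be an integer matrix")
    if (!identical(dim(object@codes), c(object@spec@nrow, object@spec@ncol)))
      msg <- c(msg, "codes dimensions must match the GridSpec")
    if (is.null(names(object@legend)) || any(names(object@legend) == ""))
      msg <- c(msg, "legend must be a fully named integer vector")
    if (anyDuplicated(object@legend))
      msg <- c(msg, "legend codes must be unique")
    bad <- setdiff(unique(object@codes[!is.na(object@codes)]), object@legend)
    if (length(bad))
      msg <- c(msg, paste0("codes absent from legend: ",
                           paste(bad, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' Default land-use legend
#'
#' Codes 1..9 assigned to the canonical classes in order.
#' @return Named integer vector.
#' @export
defaultLegend <- function() {
  stats::setNames(seq_along(landUseClasses()), landUseClasses())
}

#' Construct a LandUseGrid
#'
#' @param codes integer matrix of land-use codes, \code{NA} for nodata.
#' @param spec a \linkS4class{GridSpec}; defaulted as in
#'   \code{\link{valueGrid}}.
#' @param legend named integer vector mapping class names to codes.
#' @return A \linkS4class{LandUseGrid}.
#' @export
landUseGrid <- function(codes, spec = NULL, legend = defaultLegend()) {
  codes <- as.matrix(codes)
  if (is.double(codes)) {
    if (any(codes[!is.na(codes)] != round(codes[!is.na(codes)])))
      stop("categorical raster contains non-integer codes")
    storage.mode(codes) <- "integer"
  }
  if (is.null(spec)) spec <- gridSpec(nrow(codes), ncol(codes), 1000)
  new("LandUseGrid", spec = spec, codes = codes,
      legend = stats::setNames(as.integer(legend), names(legend)))
}

#' HDIGrid: combined disturbance index with its components
#'
#' Holds the cellwise HDI = LNI + RCI + PEI together with the three component
#' score surfaces. HDI lies in [0, 60]: LNI contributes up to 10 (one scored
#' dataset), RCI up to 20 (water + energy), PEI up to 30 (CO2 + N2O +
#' non-point).
#'
#' @slot spec the shared \linkS4class{GridSpec}.
#' @slot hdi,lni,rci,pei numeric matrices, \code{NA} = nodata.
#' @export
setClass("HDIGrid",
  representation(spec = "GridSpec", hdi = "matrix", lni = "matrix",
                 rci = "matrix", pei = "matrix"),
  validity = function(object) {
    dims <- c(object@spec@nrow, object@spec@ncol)
    for (s in c("hdi", "lni", "rci", "pei"))
      if (!identical(dim(slot(object, s)), dims))
        return(paste(s, "dimensions must match the GridSpec"))
    ok <- !is.na(object@hdi)
    if (any(object@hdi[ok] < -1e-9 | object@hdi[ok] > 60 + 1e-9))
      return("hdi must lie in [0, 60]")
    resid <- object@hdi - (object@lni + object@rci + object@pei)
    if (any(abs(resid[!is.na(resid)]) > 1e-9))
      return("hdi must equal lni + rci + pei cellwise (1e-9)")
    TRUE
  })

#' LevelGrid: 10-level disturbance classification
#'
#' Integer levels 1..10 (reported as Roman I..X), nodata preserved.
#'
#' @slot spec the \linkS4class{GridSpec}.
#' @slot levels integer matrix in 1..10, \code{NA} = nodata.
#' @export
setClass("LevelGrid",
  representation(spec = "GridSpec", levels = "matrix"),
  validity = function(object) {
    if (!is.integer(object@levels))
      return("levels must be an integer matrix")
    if (!identical(dim(object@levels), c(object@spec@nrow, object@spec@ncol)))
      return("levels dimensions must match the GridSpec")
    ok <- !is.na(object@levels)
    if (any(object@levels[ok] < 1L | object@levels[ok] > 10L))
      return("levels must lie in 1..10")
    TRUE
  })

#' SpatialWeights: sparse neighbor structure over grid cells
#'
#' Binary spatial weights over the non-nodata cells of a grid, in row-major
#' cell order. Diagonal is zero; contiguity and distance-band schemes are
#' symmetric. \code{cells} maps weight-matrix rows to linear cell indices
#' (column-major R indices into the grid matrix).
#'
#' @slot n number of cells carried.
#' @slot W sparse symmetric 0/1 matrix (\code{Matrix::dgCMatrix}).
#' @slot cells integer vector of linear indices into the grid matrix.
#' @slot scheme \code{"rook"}, \code{"queen"} or \code{"distance_band"}.
#' @slot d band distance in meters (NA unless distance_band).
#' @export
setClass("SpatialWeights",
  representation(n = "integer", W = "Matrix", cells = "integer",
                 scheme = "character", d = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@W), c(as.integer(object@n), as.integer(object@n))))
      return("W must be n x n")
    if (length(object@cells) != object@n)
      return("cells must have length n")
    if (any(Matrix::diag(object@W) != 0))
      return("W must have a zero diagonal")
    TRUE
  })

#' EmissionField: scattered or coarse-grid emission samples
#'
#' Point samples (x, y, value) of a pollutant emission field in projected
#' meters, the input to grid interpolation. A coarse raster is represented by
#' its cell-center samples (see \code{\link{asEmissionField}}).
#'
#' @slot samples data.frame with columns x, y, value.
#' @slot pollutant label, e.g. \code{"CO2"} or \code{"N2O"}.
#' @export
setClass("EmissionField",
  representation(samples = "data.frame", pollutant = "character"),
  validity = function(object) {
    s <- object@samples
    if (!all(c("x", "y", "value") %in% names(s)))
      return("samples must have columns x, y, value")
    if (nrow(s) == 0L) return("emission field is empty")
    if (!all(is.finite(s$x)) || !all(is.finite(s$y)))
      return("sample coordinates must be finite")
    if (any(s$value < 0, na.rm = TRUE))
      return("emission values must be non-negative")
    TRUE
  })

#' Construct an EmissionField from samples
#'
#' @param samples data.frame with columns \code{x}, \code{y}, \code{value}.
#' @param pollutant pollutant label.
#' @return An \linkS4class{EmissionField}.
#' @export
emissionField <- function(samples, pollutant = "CO2") {
  new("EmissionField", samples = as.data.frame(samples),
      pollutant = as.character(pollutant))
}

#' CentroidTrack: time-ordered weighted-centroid trajectory
#'
#' Centroid positions per period plus per-segment displacement (m), compass
#' bearing (degrees clockwise from north), 8-sector cardinal direction, and
#' speed (m/year).
#'
#' @slot points data.frame: period, X, Y.
#' @slot segments data.frame: from, to, displacement, bearing, direction,
#'   intervalYears, speed.
#' @export
setClass("CentroidTrack",
  representation(points = "data.frame", segments = "data.frame"),
  validity = function(object) {
    if (!all(c("period", "X", "Y") %in% names(object@points)))
      return("points must have columns period, X, Y")
    if (nrow(object@points) >= 2L &&
        nrow(object@segments) != nrow(object@points) - 1L)
      return("segments must have one row per consecutive point pair")
    TRUE
  })

#' BreaksSpec: class boundaries for score standardization
#'
#' Strictly increasing boundaries b0 < b1 < ... < bk defining k classes
#' (b_{i-1}, b_i], the first closed at b0, with integer score labels. Produced
#' by \code{\link{jenksBreaks}} or the equal-interval fallback.
#'
#' @slot boundaries numeric vector of length k + 1, strictly increasing.
#' @slot labels integer score labels, one per class.
#' @slot method \code{"jenks"} or \code{"equal_interval"}.
#' @export
setClass("BreaksSpec",
  representation(boundaries = "numeric", labels = "integer",
                 method = "character"),
  validity = function(object) {
    k <- length(object@labels)
    if (length(object@boundaries) != k + 1L)
      return("boundaries must have one more element than labels")
    # interior and upper boundaries are class maxima and must strictly
    # increase; the lower bound b0 may coincide with b1 when the first
    # class holds a single distinct value
    if (any(diff(object@boundaries[-1]) <= 0) ||
        object@boundaries[1] > object@boundaries[2])
      return("boundaries must be non-decreasing, strict after the first")
    TRUE
  })
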