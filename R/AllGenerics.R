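#' @importClassesFrom Matrix Matrix
NULL

#' Accessors for grid objects
#'
#' \code{gridSpecOf} returns the \linkS4class{GridSpec}; \code{gridValues} the
#' value matrix (\code{NA} = nodata); \code{landUseCodes} the integer code
#' matrix; \code{gridLegend} the named code vector; \code{valueUnits} the unit
#' label; \code{hdiValues} the combined index matrix of an
#' \linkS4class{HDIGrid}; \code{componentLayer} one of its components;
#' \code{levelValues} the level matrix of a \linkS4class{LevelGrid}.
#'
#' @param x a grid object.
#' @param which for \code{componentLayer}: \code{"lni"}, \code{"rci"} or
#'   \code{"pei"}.
#' @return See details above.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridSpecOf", function(x) standardGeneric("gridSpecOf"))
#' @rdname grid-accessors
#' @export
setMethod("gridSpecOf", "ValueGrid", function(x) x@spec)
#' @rdname grid-accessors
#' @export
setMethod("gridSpecOf", "LandUseGrid", function(x) x@spec)
#' @rdname grid-accessors
#' @export
setMethod("gridSpecOf", "HDIGrid", function(x) x@spec)
#' @rdname grid-accessors
#' @export
setMethod("gridSpecOf", "LevelGrid", function(x) x@spec)

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname grid-accessors
#' @export
setMethod("gridValues", "ValueGrid", function(x) x@values)

#' @rdname grid-accessors
#' @export
landUseCodes <- function(x) {
  stopifnot(is(x, "LandUseGrid"))
  x@codes
}

#' @rdname grid-accessors
#' @export
gridLegend <- function(x) {
  stopifnot(is(x, "LandUseGrid"))
  x@legend
}

#' @rdname grid-accessors
#' @export
valueUnits <- function(x) {
  stopifnot(is(x, "ValueGrid"))
  x@units
}

#' @rdname grid-accessors
#' @export
hdiValues <- function(x) {
  stopifnot(is(x, "HDIGrid"))
  x@hdi
}

#' @rdname grid-accessors
#' @export
componentLayer <- function(x, which = c("lni", "rci", "pei")) {
  stopifnot(is(x, "HDIGrid"))
  which <- match.arg(which)
  valueGrid(slot(x, which), spec = x@spec, units = "score")
}

#' @rdname grid-accessors
#' @export
levelValues <- function(x) {
  stopifnot(is(x, "LevelGrid"))
  x@levels
}

#' Number of rows/columns and cell size of a GridSpec
#'
#' @param spec a \linkS4class{GridSpec}.
#' @return \code{gridDim}: integer c(nrow, ncol); \code{cellSizeOf}: meters;
#'   \code{cellAreaKm2}: cell area in square kilometers.
#' @export
gridDim <- function(spec) c(spec@nrow, spec@ncol)

#' @rdname gridDim
#' @export
cellSizeOf <- function(spec) spec@cellSize

#' @rdname gridDim
#' @export
cellAreaKm2 <- function(spec) (spec@cellSize / 1000)^2

#' Cell-center coordinates of a grid
#'
#' Returns projected coordinates of every cell center, following the
#' convention that the 0-based cell (i, j) has center
#' x = originX + (j + 0.5) cellSize, y = originY - (i + 0.5) cellSize.
#'
#' @param spec a \linkS4class{GridSpec}.
#' @return list with matrices \code{x} and \code{y} (nrow x ncol).
#' @export
cellCenters <- function(spec) {
  xs <- spec@originX + (seq_len(spec@ncol) - 0.5) * spec@cellSize
  ys <- spec@originY - (seq_len(spec@nrow) - 0.5) * spec@cellSize
  list(x = matrix(xs, spec@nrow, spec@ncol, byrow = TRUE),
       y = matrix(ys, spec@nrow, spec@ncol))
}

#' Test whether grids share the same georeferencing
#'
#' @param a,b grid objects or \linkS4class{GridSpec}s.
#' @return logical.
#' @export
isAligned <- function(a, b) {
  sa <- if (is(a, "GridSpec")) a else gridSpecOf(a)
  sb <- if (is(b, "GridSpec")) b else gridSpecOf(b)
  sa@nrow == sb@nrow && sa@ncol == sb@ncol &&
    isTRUE(all.equal(sa@cellSize, sb@cellSize)) &&
    isTRUE(all.equal(sa@originX, sb@originX)) &&
    isTRUE(all.equal(sa@originY, sb@originY)) &&
    sa@crs == sb@crs
}

.stopifNotAligned <- function(..., what = "grids") {
  gs <- list(...)
  for (g in gs[-1])
    if (!isAligned(gs[[1]], g))
      stop("alignment error: ", what, " do not share the same GridSpec")
  invisible(TRUE)
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g), crs '%s'\n",
              object@nrow, object@ncol, object@cellSize,
              object@originX, object@originY, object@crs))
})

setMethod("show", "ValueGrid", function(object) {
  v <- object@values
  cat(sprintf("ValueGrid [%s]\n", if (nzchar(object@units)) object@units
              else "unitless"))
  show(object@spec)
  cat(sprintf("  %d nodata cells; range of data: [%s, %s]\n",
              sum(is.na(v)),
              if (all(is.na(v))) "-" else format(min(v, na.rm = TRUE)),
              if (all(is.na(v))) "-" else format(max(v, na.rm = TRUE))))
})

setMethod("show", "LandUseGrid", function(object) {
  cat("LandUseGrid\n")
  show(object@spec)
  tab <- table(factor(object@codes, levels = object@legend,
                      labels = names(object@legend)))
  tab <- tab[tab > 0]
  cat("  classes present:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "HDIGrid", function(object) {
  cat("HDIGrid (HDI = LNI + RCI + PEI)\n")
  show(object@spec)
  ok <- !is.na(object@hdi)
  if (any(ok))
    cat(sprintf("  HDI range [%.2f, %.2f], mean %.2f over %d cells\n",
                min(object@hdi[ok]), max(object@hdi[ok]),
                mean(object@hdi[ok]), sum(ok)))
})

setMethod("show", "LevelGrid", function(object) {
  cat("LevelGrid (disturbance levels I..X)\n")
  show(object@spec)
})

setMethod("show", "SpatialWeights", function(object) {
  cat(sprintf("SpatialWeights: %d cells, scheme '%s'%s, %d links\n",
              object@n, object@scheme,
              if (object@scheme == "distance_band")
                sprintf(" (d = %g m)", object@d) else "",
              as.integer(Matrix::nnzero(object@W))))
})

setMethod("show", "EmissionField", function(object) {
  cat(sprintf("EmissionField '%s': %d samples, total %g\n", object@pollutant,
              nrow(object@samples), sum(object@samples$value)))
})

setMethod("show", "CentroidTrack", function(object) {
  cat(sprintf("CentroidTrack: %d points, %d segments\n",
              nrow(object@points), nrow(object@segments)))
  if (nrow(object@segments)) print(object@segments, row.names = FALSE)
})

#' Track accessors
#'
#' @param x a \linkS4class{CentroidTrack}.
#' @return data.frame of centroid points / per-segment kinematics.
#' @export
trackPoints <- function(x) {
  stopifnot(is(x, "CentroidTrack"))
  x@points
}

#' @rdname trackPoints
#' @export
trackSegments <- function(x) {
  stopifnot(is(x, "CentroidTrack"))
  x@segments
}

#' Arithmetic on aligned ValueGrids
#'
#' Cellwise arithmetic between two aligned ValueGrids or a ValueGrid and a
#' scalar; nodata (NA) propagates.
#'
#' @param e1,e2 operands.
#' @return A \linkS4class{ValueGrid}.
#' @name ValueGrid-arith
#' @aliases Arith,ValueGrid,ValueGrid-method
#' @export
setMethod("Arith", signature("ValueGrid", "ValueGrid"), function(e1, e2) {
  .stopifNotAligned(e1, e2)
  valueGrid(callGeneric(e1@values, e2@values), spec = e1@spec,
            units = e1@units)
})

#' @rdname ValueGrid-arith
#' @aliases Arith,ValueGrid,numeric-method
#' @export
setMethod("Arith", signature("ValueGrid", "numeric"), function(e1, e2) {
  valueGrid(callGeneric(e1@values, e2), spec = e1@spec, units = e1@units)
})

#' @rdname ValueGrid-arith
#' @aliases Arith,numeric,ValueGrid-method
#' @export
setMethod("Arith", signature("numeric", "ValueGrid"), function(e1, e2) {
  valueGrid(callGeneric(e1, e2@values), spec = e2@spec, units = e2@units)
})
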