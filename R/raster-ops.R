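#' Align grids onto a common GridSpec
#'
#' Resamples each grid onto \code{target}. Categorical grids are always
#' resampled nearest-neighbor; continuous grids use \code{method}. Grids
#' already on the target spec are returned unchanged (alignment is
#' idempotent). No reprojection is performed: a CRS label mismatch is an
#' error.
#'
#' @param grids a single grid or a list of \linkS4class{ValueGrid} /
#'   \linkS4class{LandUseGrid}.
#' @param target target \linkS4class{GridSpec}.
#' @param method \code{"nearest"} or \code{"bilinear"} (continuous only).
#' @return A list of aligned grids (or a single grid if a single grid was
#'   given).
#' @export
alignGrids <- function(grids, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  single <- !is.list(grids)
  if (single) grids <- list(grids)
  out <- lapply(grids, function(g) {
    spec <- gridSpecOf(g)
    if (spec@crs != target@crs)
      stop("alignment error: CRS mismatch ('", spec@crs, "' vs '",
           target@crs, "'); no implicit reprojection")
    if (isAligned(spec, target)) return(g)
    if (is(g, "LandUseGrid")) {
      landUseGrid(.resampleNearest(g@codes, spec, target), spec = target,
                  legend = g@legend)
    } else if (method == "nearest") {
      valueGrid(.resampleNearest(g@values, spec, target), spec = target,
                units = g@units)
    } else {
      valueGrid(.resampleBilinear(g@values, spec, target), spec = target,
                units = g@units)
    }
  })
  if (single) out[[1]] else out
}

# Map target cell centers into source index space (1-based, fractional).
.sourceIndex <- function(src, target) {
  tx <- target@originX + (seq_len(target@ncol) - 0.5) * target@cellSize
  ty <- target@originY - (seq_len(target@nrow) - 0.5) * target@cellSize
  list(col = (tx - src@originX) / src@cellSize + 0.5,
       row = (src@originY - ty) / src@cellSize + 0.5)
}

.resampleNearest <- function(m, src, target) {
  idx <- .sourceIndex(src, target)
  ri <- pmin(pmax(round(idx$row), 1L), nrow(m))
  ci <- pmin(pmax(round(idx$col), 1L), ncol(m))
  # outside the source extent entirely -> nodata
  offR <- idx$row < 0.5 | idx$row > nrow(m) + 0.5
  offC <- idx$col < 0.5 | idx$col > ncol(m) + 0.5
  out <- m[ri, ci, drop = FALSE]
  out[offR, ] <- NA
  out[, offC] <- NA
  out
}

.resampleBilinear <- function(m, src, target) {
  idx <- .sourceIndex(src, target)
  r <- idx$row; cl <- idx$col
  r0 <- pmin(pmax(floor(r), 1L), nrow(m)); r1 <- pmin(r0 + 1L, nrow(m))
  c0 <- pmin(pmax(floor(cl), 1L), ncol(m)); c1 <- pmin(c0 + 1L, ncol(m))
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(cl - c0, 0), 1)
  out <- matrix(NA_real_, target@nrow, target@ncol)
  for (i in seq_len(target@nrow)) {
    a <- m[r0[i], c0] * (1 - fc) + m[r0[i], c1] * fc
    b <- m[r1[i], c0] * (1 - fc) + m[r1[i], c1] * fc
    out[i, ] <- a * (1 - fr[i]) + b * fr[i]
  }
  offR <- r < 0.5 | r > nrow(m) + 0.5
  offC <- cl < 0.5 | cl > ncol(m) + 0.5
  out[offR, ] <- NA
  out[, offC] <- NA
  out
}

#' Mask a grid to one zone
#'
#' Cells outside the zone become nodata; values inside are unchanged.
#'
#' @param grid a \linkS4class{ValueGrid}.
#' @param zones an aligned integer zone raster (\linkS4class{ValueGrid} or
#'   \linkS4class{LandUseGrid}).
#' @param zoneId the zone to keep.
#' @return A \linkS4class{ValueGrid}.
#' @export
zonalMask <- function(grid, zones, zoneId) {
  .stopifNotAligned(grid, zones)
  zm <- if (is(zones, "LandUseGrid")) zones@codes else zones@values
  keep <- !is.na(zm) & zm == zoneId
  if (!any(keep)) stop("empty-zone error: zone ", zoneId,
                       " has no cells in the zone raster")
  v <- grid@values
  v[!keep] <- NA
  valueGrid(v, spec = grid@spec, units = grid@units)
}

#' Sum of a surface over the grid, in quantity units
#'
#' Integrates a per-area density surface: sum of cell values times cell area
#' (km^2). With \code{density = FALSE} the plain cell sum is returned.
#'
#' @param grid a \linkS4class{ValueGrid}.
#' @param density if TRUE values are treated as per-km^2 densities.
#' @return numeric scalar.
#' @export
gridTotal <- function(grid, density = TRUE) {
  s <- sum(grid@values, na.rm = TRUE)
  if (density) s * cellAreaKm2(grid@spec) else s
}

#' Cell counts and areas by land-use class
#'
#' @param landUse a \linkS4class{LandUseGrid}.
#' @return data.frame: class, cells, areaKm2 (all legend classes, zeros kept).
#' @export
classAreas <- function(landUse) {
  tab <- table(factor(landUse@codes, levels = landUse@legend,
                      labels = names(landUse@legend)))
  data.frame(class = names(tab), cells = as.integer(tab),
             areaKm2 = as.integer(tab) * cellAreaKm2(landUse@spec),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Logical mask of cells belonging to given classes
#'
#' @param landUse a \linkS4class{LandUseGrid}.
#' @param classes character vector of class names.
#' @return logical matrix (FALSE on nodata).
#' @export
classMask <- function(landUse, classes) {
  unknown <- setdiff(classes, names(landUse@legend))
  if (length(unknown))
    stop("unknown land-use class(es): ", paste(unknown, collapse = ", "))
  m <- matrix(FALSE, nrow(landUse@codes), ncol(landUse@codes))
  codes <- landUse@legend[classes]
  m[!is.na(landUse@codes) & landUse@codes %in% codes] <- TRUE
  m
}

#' Cellwise mean of a list of aligned ValueGrids
#'
#' The temporal-averaging primitive for gridded inputs (e.g. 5-year mean
#' emission surfaces). Nodata propagates: a cell that is nodata in any year is
#' nodata in the mean.
#'
#' @param grids list of aligned \linkS4class{ValueGrid}s.
#' @return A \linkS4class{ValueGrid}.
#' @export
meanGrid <- function(grids) {
  stopifnot(length(grids) >= 1L)
  do.call(.stopifNotAligned, grids)
  acc <- grids[[1]]@values
  for (g in grids[-1]) acc <- acc + g@values
  valueGrid(acc / length(grids), spec = grids[[1]]@spec,
            units = grids[[1]]@units)
}
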