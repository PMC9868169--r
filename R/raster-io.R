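#' Read a raster from an ESRI ASCII grid file
#'
#' Reads the plain-text ESRI ASCII grid interchange format (.asc). This is the
#' package's raster format: it is text, self-describing, and supported by all
#' GIS software. The CRS is not part of the format and is supplied as an
#' opaque label.
#'
#' @param path path to the .asc file.
#' @param kind \code{"continuous"} (returns a \linkS4class{ValueGrid}) or
#'   \code{"categorical"} (returns a \linkS4class{LandUseGrid}; non-integer
#'   band values are rejected).
#' @param legend for categorical reads, named integer vector mapping class
#'   names to codes; any code in the file absent from the legend is an error
#'   naming the code.
#' @param units unit label attached to continuous reads.
#' @param crs CRS label attached to the grid.
#' @return A \linkS4class{ValueGrid} or \linkS4class{LandUseGrid}.
#' @seealso \code{\link{writeRaster}}
#' @export
readRaster <- function(path, kind = c("continuous", "categorical"),
                       legend = defaultLegend(), units = "", crs = "local-m") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header incomplete in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ESRI ASCII body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  spec <- gridSpec(nr, nc, hdr$cellsize, originX = xll,
                   originY = yll + nr * hdr$cellsize, crs = crs)
  if (kind == "continuous") return(valueGrid(m, spec = spec, units = units))
  nonint <- !is.na(m) & m != round(m)
  if (any(nonint))
    stop("categorical raster contains non-integer values, e.g. ",
         m[which(nonint)[1]])
  bad <- setdiff(unique(m[!is.na(m)]), legend)
  if (length(bad))
    stop("legend error: land-use code(s) not in legend: ",
         paste(sort(bad), collapse = ", "))
  landUseGrid(m, spec = spec, legend = legend)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Continuous values are written with 17 significant digits so that a
#' write-read round trip is value-preserving.
#'
#' @param grid a \linkS4class{ValueGrid} or \linkS4class{LandUseGrid}.
#' @param path output path (.asc).
#' @param nodata sentinel written for \code{NA} cells.
#' @return \code{path}, invisibly.
#' @export
writeRaster <- function(grid, path, nodata = -9999) {
  spec <- gridSpecOf(grid)
  m <- if (is(grid, "LandUseGrid")) grid@codes else grid@values
  if (any(m == nodata, na.rm = TRUE))
    stop("nodata sentinel ", nodata, " collides with a data value")
  hdr <- c(sprintf("ncols %d", spec@ncol),
           sprintf("nrows %d", spec@nrow),
           sprintf("xllcorner %.17g", spec@originX),
           sprintf("yllcorner %.17g", spec@originY - spec@nrow * spec@cellSize),
           sprintf("cellsize %.17g", spec@cellSize),
           sprintf("NODATA_value %.17g", nodata))
  fmt <- if (is.integer(m)) "%d" else "%.17g"
  m2 <- m
  m2[is.na(m2)] <- nodata
  rows <- apply(m2, 1L, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Rasterize GeoJSON zone polygons onto a grid
#'
#' Burns polygon features of a GeoJSON FeatureCollection into an integer zone
#' raster by an even-odd ray-casting point-in-polygon test on cell centers.
#' Coordinates must be in the same projected CRS as the grid. Each feature's
#' zone id is taken from the property named by \code{idProperty}, falling back
#' to the feature's position.
#'
#' @param geojson path to a GeoJSON file, or an already-parsed list.
#' @param spec target \linkS4class{GridSpec}.
#' @param idProperty feature property carrying the integer zone id.
#' @return A \linkS4class{ValueGrid} of integer zone ids (NA outside all
#'   polygons).
#' @export
rasterizeZones <- function(geojson, spec, idProperty = "zone") {
  gj <- if (is.character(geojson))
    jsonlite::fromJSON(geojson, simplifyVector = FALSE) else geojson
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  cc <- cellCenters(spec)
  out <- matrix(NA_real_, spec@nrow, spec@ncol)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    id <- f$properties[[idProperty]]
    if (is.null(id)) id <- k
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    inside <- rep(FALSE, length(px))
    for (poly in polys) for (ring in poly) {
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
      inside <- xor(inside, .pointInRing(px, py, xs, ys))
    }
    out[inside] <- as.numeric(id)
  }
  valueGrid(out, spec = spec, units = "zone")
}

# Even-odd rule; points exactly on an edge are resolved by the half-open
# crossing test (consistent, not symmetric).
.pointInRing <- function(px, py, xs, ys) {
  n <- length(xs)
  if (n > 1 && xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
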