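#' Build a spatial weights structure over grid cells
#'
#' Binary weights over the non-nodata cells of a grid: \code{"rook"}
#' (edge-sharing neighbors), \code{"queen"} (edge or corner), or
#' \code{"distance_band"} (cell centers within 0 < distance <= d meters).
#' The structure is symmetric with a zero diagonal.
#'
#' @param spec a \linkS4class{GridSpec}.
#' @param mask logical matrix of cells to include (default: all).
#' @param scheme \code{"queen"}, \code{"rook"} or \code{"distance_band"}.
#' @param d band distance in meters (distance_band only; must be >=
#'   cellSize or every neighborhood is empty).
#' @return A \linkS4class{SpatialWeights}.
#' @export
buildWeights <- function(spec, mask = NULL,
                         scheme = c("queen", "rook", "distance_band"),
                         d = NULL) {
  scheme <- match.arg(scheme)
  nr <- spec@nrow; nc <- spec@ncol
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(identical(dim(mask), c(nr, nc)))
  cells <- which(mask)  # linear column-major indices
  n <- length(cells)
  if (n < 2L) stop("need at least 2 cells to build weights")
  id <- matrix(NA_integer_, nr, nc)
  id[cells] <- seq_len(n)
  ri <- ((cells - 1L) %% nr) + 1L
  ci <- ((cells - 1L) %/% nr) + 1L

  offsets <- switch(scheme,
    rook = cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L)),
    queen = {
      g <- expand.grid(dr = -1:1, dc = -1:1)
      as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
    },
    distance_band = {
      if (is.null(d)) stop("distance_band needs a band distance d")
      if (d < spec@cellSize)
        stop("empty-neighborhood error: d = ", d, " m is below the cell size")
      r <- min(floor(d / spec@cellSize), max(nr, nc))
      g <- expand.grid(dr = -r:r, dc = -r:r)
      keep <- (g$dr^2 + g$dc^2) * spec@cellSize^2 <= d^2 &
        !(g$dr == 0 & g$dc == 0)
      as.matrix(g[keep, ])
    })

  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    r2 <- ri + offsets[k, 1]; c2 <- ci + offsets[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- rep(NA_integer_, n)
    j[ok] <- id[cbind(r2[ok], c2[ok])]
    has <- !is.na(j)
    ii <- c(ii, seq_len(n)[has]); jj <- c(jj, j[has])
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  new("SpatialWeights", n = n, W = W, cells = cells, scheme = scheme,
      d = if (scheme == "distance_band") as.numeric(d) else NA_real_)
}

#' Neighbor counts of a weights structure
#' @param w a \linkS4class{SpatialWeights}.
#' @return integer vector of per-cell neighbor counts.
#' @export
neighborCounts <- function(w) as.integer(Matrix::rowSums(w@W))

.cellValues <- function(x, w) {
  v <- if (is(x, "HDIGrid")) x@hdi else if (is(x, "ValueGrid")) x@values
       else x
  if (is.matrix(v)) v <- v[w@cells]
  if (length(v) != w@n)
    stop("values length does not match the weights structure")
  if (anyNA(v)) stop("values carry NA on cells included in the weights")
  v
}

#' Global Moran's I
#'
#' I = sum_ij W_ij (x_i - xbar)(x_j - xbar) / (S^2 sum_ij W_ij) with S^2 the
#' population variance (divide by n). Binary weights, no row
#' standardization. On a rook-weighted checkerboard this is exactly -1.
#'
#' @param x a \linkS4class{ValueGrid}, \linkS4class{HDIGrid}, or numeric
#'   vector over the weights' cells.
#' @param w a \linkS4class{SpatialWeights}.
#' @return numeric scalar.
#' @export
moransI <- function(x, w) {
  v <- .cellValues(x, w)
  if (stats::var(v) == 0)
    stop("degenerate-field error: zero variance, Moran's I undefined")
  z <- v - mean(v)
  num <- as.numeric(Matrix::crossprod(z, w@W %*% z))
  s2 <- mean(z^2)
  num / (s2 * Matrix::nnzero(w@W))
}

#' Moran's I significance test
#'
#' Z = (I - E[I]) / sqrt(Var[I]) with E[I] = -1/(n-1). Under
#' \code{method = "normality"} the variance is the closed form for a normal
#' field; \code{method = "permutation"} draws seeded random relabelings and
#' reports the permutation z and pseudo p-value. p is two-sided.
#'
#' @inheritParams moransI
#' @param method \code{"normality"} or \code{"permutation"}.
#' @param nperm permutations (permutation method).
#' @param seed RNG seed for the permutation draw.
#' @return list: I, expectation, variance, Z, p, method (plus \code{permI},
#'   the permuted values, for the permutation method).
#' @export
moranZ <- function(x, w, method = c("normality", "permutation"),
                   nperm = 999L, seed = 1L) {
  method <- match.arg(method)
  v <- .cellValues(x, w)
  n <- length(v)
  I <- moransI(v, w)
  EI <- -1 / (n - 1)
  if (method == "normality") {
    W <- w@W
    S0 <- Matrix::nnzero(W)  # binary weights: sum of w_ij
    S1 <- sum((W + Matrix::t(W))@x^2) / 2
    rs <- Matrix::rowSums(W); cs <- Matrix::colSums(W)
    S2 <- sum((rs + cs)^2)
    varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
    Z <- (I - EI) / sqrt(varI)
    list(I = I, expectation = EI, variance = varI, Z = Z,
         p = 2 * stats::pnorm(-abs(Z)), method = method)
  } else {
    permI <- withSeed(seed, {
      vapply(seq_len(nperm), function(i) moransI(sample(v), w), 0)
    })
    m <- mean(permI); s <- stats::sd(permI)
    Z <- (I - m) / s
    p <- (1 + sum(abs(permI - m) >= abs(I - m))) / (nperm + 1)
    list(I = I, expectation = m, variance = s^2, Z = Z, p = p,
         method = method, permI = permI)
  }
}

#' HDI-weighted centroid of a grid
#'
#' X = sum(x_ij HDI_ij) / sum(HDI_ij) and likewise Y over non-nodata cells,
#' with cell-center coordinates. Invariant under positive rescaling of the
#' values and equivariant under origin translation.
#'
#' @param x an \linkS4class{HDIGrid} or \linkS4class{ValueGrid}.
#' @return named numeric c(X, Y) in projected meters.
#' @export
weightedCentroid <- function(x) {
  v <- if (is(x, "HDIGrid")) x@hdi else x@values
  spec <- gridSpecOf(x)
  ok <- !is.na(v)
  tot <- sum(v[ok])
  if (!any(ok) || tot <= 0)
    stop("undefined-centroid error: no positive values")
  cc <- cellCenters(spec)
  c(X = sum(cc$x[ok] * v[ok]) / tot, Y = sum(cc$y[ok] * v[ok]) / tot)
}

.bearing <- function(dx, dy) (atan2(dx, dy) * 180 / pi) %% 360

.direction8 <- function(bearing) {
  labs <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  labs[(floor((bearing + 22.5) / 45) %% 8) + 1]
}

#' Centroid migration track
#'
#' Per consecutive pair of centroids: Euclidean displacement (m), compass
#' bearing (degrees clockwise from north) with its 8-sector cardinal label,
#' and speed = displacement / interval (m/year). Intervals are the actual
#' year spans between periods.
#'
#' @param centroids data.frame with columns \code{period}, \code{X},
#'   \code{Y}, time-ordered (>= 2 rows).
#' @param intervalYears numeric vector of segment lengths in years (length
#'   nrow - 1), all > 0.
#' @return A \linkS4class{CentroidTrack}.
#' @examples
#' ct <- centroidTrack(
#'   data.frame(period = c("2010", "2015"), X = c(0, -426.25), Y = c(0, -426.25)),
#'   intervalYears = 5)
#' trackSegments(ct)  # 602.80 m to the SW at 120.56 m/year
#' @export
centroidTrack <- function(centroids, intervalYears) {
  stopifnot(nrow(centroids) >= 2L)
  if (length(intervalYears) != nrow(centroids) - 1L)
    stop("intervalYears must have one entry per consecutive pair")
  if (any(intervalYears <= 0))
    stop("input error: non-positive interval")
  dx <- diff(centroids$X); dy <- diff(centroids$Y)
  disp <- sqrt(dx^2 + dy^2)
  brg <- ifelse(disp == 0, NA_real_, .bearing(dx, dy))
  seg <- data.frame(
    from = centroids$period[-nrow(centroids)],
    to = centroids$period[-1],
    displacement = disp,
    bearing = brg,
    direction = ifelse(is.na(brg), "", .direction8(brg)),
    intervalYears = as.numeric(intervalYears),
    speed = disp / intervalYears,
    stringsAsFactors = FALSE)
  new("CentroidTrack", points = as.data.frame(centroids), segments = seg)
}

#' Getis-Ord Gi* hot- and cold-spot detection
#'
#' Computes the Gi* statistic with binary distance-band weights INCLUDING
#' the self term (W_ii = 1): Gi* = sum_j W_ij(d) x_j / sum_j x_j over all
#' cells j. The z-score uses the standardized Gi* moments under the
#' randomization null,
#' Z_i = (sum_j w_ij x_j - xbar W_i) / (S sqrt((n W_i - W_i^2) / (n - 1)))
#' with W_i the neighborhood size and S the population standard deviation.
#' Cells are categorized by the usual confidence thresholds |Z| >= 1.645
#' (90\%), 1.960 (95\%), 2.576 (99\%). A constant field yields Z = 0 and
#' \code{not_significant} everywhere by convention (with a message).
#'
#' @param x a \linkS4class{ValueGrid} or \linkS4class{HDIGrid} of
#'   non-negative values (nodata cells are excluded).
#' @param d band distance in meters; default 2 * cellSize.
#' @return list with \code{giStar}, \code{z} and \code{category} matrices on
#'   the grid, plus the \linkS4class{SpatialWeights} used (self term not
#'   stored). Categories: cold99, cold95, cold90, not_significant, hot90,
#'   hot95, hot99.
#' @export
getisOrdGiStar <- function(x, d = NULL) {
  v <- if (is(x, "HDIGrid")) x@hdi else x@values
  spec <- gridSpecOf(x)
  if (is.null(d)) d <- 2 * spec@cellSize
  if (any(v < 0, na.rm = TRUE)) stop("Gi* expects non-negative values")
  mask <- !is.na(v)
  if (sum(v[mask]) <= 0) stop("degenerate error: zero-sum field")
  w <- buildWeights(spec, mask, scheme = "distance_band", d = d)
  vals <- v[w@cells]
  n <- w@n
  Wself <- w@W + Matrix::Diagonal(n)  # self term
  num <- as.numeric(Wself %*% vals)
  gi <- num / sum(vals)
  Wi <- as.numeric(Matrix::rowSums(Wself))
  xbar <- mean(vals)
  S <- sqrt(mean(vals^2) - xbar^2)
  giM <- zM <- matrix(NA_real_, spec@nrow, spec@ncol)
  giM[w@cells] <- gi
  if (S == 0) {
    message("constant field: all Gi* z-scores set to 0 by convention")
    z <- rep(0, n)
  } else {
    denom <- S * sqrt(pmax(n * Wi - Wi^2, 0) / (n - 1))
    z <- ifelse(denom == 0, 0, (num - xbar * Wi) / denom)
  }
  zM[w@cells] <- z
  cat <- matrix(NA_character_, spec@nrow, spec@ncol)
  cat[w@cells] <- cut(z,
    breaks = c(-Inf, -2.576, -1.960, -1.645, 1.645, 1.960, 2.576, Inf),
    labels = c("cold99", "cold95", "cold90", "not_significant",
               "hot90", "hot95", "hot99"),
    right = FALSE) |> as.character()
  list(giStar = giM, z = zM, category = cat, weights = w, d = d)
}
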