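#' Convert a coarse ValueGrid to an EmissionField
#'
#' Takes cell centers of non-nodata cells as point samples, the form consumed
#' by \code{\link{interpolateToGrid}}.
#'
#' @param grid a \linkS4class{ValueGrid} of non-negative emissions.
#' @param pollutant pollutant label.
#' @return An \linkS4class{EmissionField}.
#' @export
asEmissionField <- function(grid, pollutant = "CO2") {
  cc <- cellCenters(grid@spec)
  ok <- !is.na(grid@values)
  if (!any(ok)) stop("input error: emission grid is all nodata")
  emissionField(data.frame(x = cc$x[ok], y = cc$y[ok],
                           value = grid@values[ok]),
                pollutant = pollutant)
}

#' Interpolate an emission field onto a grid
#'
#' Upsamples scattered or coarse-grid emission samples to the analysis
#' resolution. Ordinary kriging (default) fits an exponential variogram to
#' the empirical semivariogram by weighted least squares (Cressie weights,
#' zero nugget) and solves the ordinary-kriging system; with zero nugget it
#' reproduces sample values at sample locations. If the kriging system is
#' singular (e.g. duplicate locations) the method falls back to
#' inverse-distance weighting with a warning. Negative interpolation
#' artifacts are clamped to zero with a message, since emissions are
#' physically non-negative.
#'
#' @param field an \linkS4class{EmissionField} (>= 5 samples for kriging,
#'   >= 1 for idw).
#' @param target target \linkS4class{GridSpec}.
#' @param method \code{"ordinary_kriging"} or \code{"idw"}.
#' @param idwPower inverse-distance power (default 2).
#' @param maxSamples kriging is solved on at most this many samples (random
#'   thinning, seeded deterministically from the sample count) to bound the
#'   dense solve.
#' @return A \linkS4class{ValueGrid} on \code{target}.
#' @export
interpolateToGrid <- function(field, target,
                              method = c("ordinary_kriging", "idw"),
                              idwPower = 2, maxSamples = 600L) {
  method <- match.arg(method)
  s <- field@samples
  if (nrow(s) == 0L) stop("input error: empty emission field")
  if (method == "ordinary_kriging" && nrow(s) < 5L)
    stop("ordinary kriging needs at least 5 samples (", nrow(s), " given)")
  cc <- cellCenters(target)
  px <- as.vector(cc$x); py <- as.vector(cc$y)

  if (nrow(s) == 1L || stats::var(s$value) == 0) {
    out <- matrix(s$value[1], target@nrow, target@ncol)
    return(valueGrid(out, spec = target, units = ""))
  }
  if (method == "ordinary_kriging" && nrow(s) > maxSamples) {
    idx <- round(seq(1L, nrow(s), length.out = maxSamples))
    s <- s[idx, , drop = FALSE]
  }

  pred <- if (method == "idw") .idw(s, px, py, idwPower) else {
    vg <- .fitExponentialVariogram(s)
    p <- tryCatch(.ordinaryKriging(s, px, py, vg),
                  error = function(e) {
                    warning("kriging system singular (", conditionMessage(e),
                            "); falling back to idw")
                    .idw(s, px, py, idwPower)
                  })
    p
  }
  nneg <- sum(pred < 0)
  if (nneg > 0) {
    message("clamped ", nneg, " negative interpolated cell(s) to 0")
    pred[pred < 0] <- 0
  }
  valueGrid(matrix(pred, target@nrow, target@ncol), spec = target, units = "")
}

# Empirical semivariogram + WLS exponential fit:
# gamma(h) = sill * (1 - exp(-h / range)), nugget 0.
.fitExponentialVariogram <- function(s, nbins = 12L) {
  n <- nrow(s)
  dx <- outer(s$x, s$x, "-"); dy <- outer(s$y, s$y, "-")
  h <- sqrt(dx^2 + dy^2)
  g <- 0.5 * outer(s$value, s$value, "-")^2
  up <- upper.tri(h)
  h <- h[up]; g <- g[up]
  hmax <- max(h) / 2
  keep <- h > 0 & h <= hmax
  if (!any(keep)) keep <- h > 0
  h <- h[keep]; g <- g[keep]
  brks <- seq(0, max(h), length.out = nbins + 1L)
  bin <- cut(h, brks, include.lowest = TRUE)
  hb <- tapply(h, bin, mean); gb <- tapply(g, bin, mean)
  nb <- tapply(g, bin, length)
  ok <- !is.na(hb) & gb > 0
  hb <- hb[ok]; gb <- gb[ok]; nb <- nb[ok]
  svar <- stats::var(s$value)
  obj <- function(p) {
    sill <- exp(p[1]); rng <- exp(p[2])
    gm <- sill * (1 - exp(-hb / rng))
    sum(nb * (gb - gm)^2 / pmax(gm, 1e-12 * svar)^2)
  }
  init <- c(log(max(gb)), log(max(hb) / 3))
  fit <- stats::optim(init, obj, method = "Nelder-Mead")
  list(sill = exp(fit$par[1]), range = exp(fit$par[2]))
}

.gammaExp <- function(h, vg) vg$sill * (1 - exp(-h / vg$range))

.ordinaryKriging <- function(s, px, py, vg) {
  n <- nrow(s)
  h <- sqrt(outer(s$x, s$x, "-")^2 + outer(s$y, s$y, "-")^2)
  A <- rbind(cbind(.gammaExp(h, vg), 1), c(rep(1, n), 0))
  h0 <- sqrt(outer(s$x, px, "-")^2 + outer(s$y, py, "-")^2)
  B <- rbind(.gammaExp(h0, vg), 1)
  lambda <- solve(A, B)          # (n+1) x m; singularity propagates as error
  as.vector(crossprod(lambda[seq_len(n), , drop = FALSE], s$value))
}

.idw <- function(s, px, py, power) {
  out <- numeric(length(px))
  # chunked to keep the m x n distance matrix modest
  chunk <- max(1L, floor(2e6 / nrow(s)))
  for (start in seq(1L, length(px), by = chunk)) {
    ii <- start:min(start + chunk - 1L, length(px))
    d2 <- outer(px[ii], s$x, "-")^2 + outer(py[ii], s$y, "-")^2
    w <- 1 / pmax(d2, 1e-300)^(power / 2)
    hit <- d2 < 1e-12
    pred <- rowSums(w * rep(s$value, each = length(ii))) / rowSums(w)
    atSample <- which(rowSums(hit) > 0)
    for (k in atSample)
      pred[k] <- s$value[which(hit[k, ])[1]]
    out[ii] <- pred
  }
  out
}

#' Non-point source pollution surface
#'
#' Non-point pollution is confined to rural and arable land: rural cells emit
#' population density times the per-capita rural emission rate; arable cells
#' emit the fertilizer application rate times the fraction of fertilizer not
#' effectively used, \code{arableApplicationRate * (1 - fertilizerUseRate)};
#' every other class is exactly 0.
#'
#' @param landUse aligned \linkS4class{LandUseGrid}.
#' @param population aligned \linkS4class{ValueGrid} (persons/km^2).
#' @param params list with \code{perCapitaRural} (mass/person/year),
#'   \code{fertilizerUseRate} (fraction in (0, 1]), and
#'   \code{arableApplicationRate} (mass/km^2/year).
#' @return A \linkS4class{ValueGrid} (mass/km^2/year).
#' @export
nonpointEmissionSurface <- function(landUse, population, params) {
  .stopifNotAligned(landUse, population)
  p <- as.list(params)
  if (is.null(p$perCapitaRural) || p$perCapitaRural <= 0 ||
      is.null(p$fertilizerUseRate) || p$fertilizerUseRate <= 0 ||
      p$fertilizerUseRate > 1 ||
      is.null(p$arableApplicationRate) || p$arableApplicationRate <= 0)
    stop("input error: non-point parameters out of range")
  if (any(population@values < 0, na.rm = TRUE))
    stop("input error: negative population density")
  v <- matrix(0, landUse@spec@nrow, landUse@spec@ncol)
  v[is.na(landUse@codes)] <- NA
  r <- classMask(landUse, "rural")
  a <- classMask(landUse, "arable")
  v[r] <- ifelse(is.na(population@values[r]), NA,
                 population@values[r] * p$perCapitaRural)
  v[a] <- p$arableApplicationRate * (1 - p$fertilizerUseRate)
  valueGrid(v, spec = landUse@spec, units = "mass/km2/yr")
}

#' Land cover indicator of non-point pollution pressure
#'
#' Min-max rescaling of an emission surface to [0, 1] over non-nodata cells;
#' a constant surface maps to all zeros. Rank-preserving and invariant under
#' positive affine rescaling of the input.
#'
#' @param surface non-negative \linkS4class{ValueGrid}.
#' @return A \linkS4class{ValueGrid} in [0, 1].
#' @export
landCoverIndicator <- function(surface) {
  v <- surface@values
  if (all(is.na(v))) stop("input error: all-nodata surface")
  if (any(v < 0, na.rm = TRUE)) stop("surface must be non-negative")
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  out <- if (hi == lo) ifelse(is.na(v), NA, 0) else (v - lo) / (hi - lo)
  valueGrid(out, spec = surface@spec, units = "lci")
}

#' Assemble the three pollutant-emission component surfaces
#'
#' Pass-through contract over aligned per-period surfaces (temporal averaging
#' is applied upstream with \code{\link{meanGrid}}): validates alignment and
#' returns the CO2, N2O and non-point surfaces ready for standardization.
#'
#' @param co2,n2o,nonpoint aligned \linkS4class{ValueGrid}s.
#' @return named list of the three ValueGrids.
#' @export
buildPeiComponents <- function(co2, n2o, nonpoint) {
  .stopifNotAligned(co2, n2o, nonpoint)
  list(co2 = co2, n2o = n2o, nonpoint = nonpoint)
}
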