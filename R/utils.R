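#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded generators never perturb user
#' code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# Separable Gaussian smoothing of a matrix with edge renormalization
# (kernel mass is rescaled at the borders, so a constant field stays
# constant). sigma is in cell units; sigma = 0 returns the input.
.smoothField <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  smooth1 <- function(nsize) {
    K <- matrix(0, nsize, nsize)
    for (i in seq_len(nsize)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= nsize
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K
  }
  Kr <- smooth1(nrow(m))
  Kc <- smooth1(ncol(m))
  Kr %*% m %*% t(Kc)
}

# Format a number for user-facing messages
.fmt <- function(x, digits = 4) formatC(x, format = "g", digits = digits)
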