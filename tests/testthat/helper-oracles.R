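# Independent brute-force oracles, deliberately naive so they share no code
# path with the package implementations.

# Moran's I as a literal double sum over a dense weight matrix.
bruteMoranI <- function(values, Wdense) {
  n <- length(values)
  xbar <- mean(values)
  z <- values - xbar
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + Wdense[i, j] * z[i] * z[j]
  s2 <- sum(z^2) / n
  num / (s2 * sum(Wdense))
}

# Pairwise O(n^2) neighbor scan over cell centers.
bruteNeighborMatrix <- function(spec, mask, scheme, d = NULL) {
  cc <- hdindex::cellCenters(spec)
  cells <- which(mask)
  x <- cc$x[cells]; y <- cc$y[cells]
  n <- length(cells)
  W <- matrix(0, n, n)
  cs <- hdindex::cellSizeOf(spec)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- abs(x[i] - x[j]) / cs
    dy <- abs(y[i] - y[j]) / cs
    W[i, j] <- switch(scheme,
      rook = as.numeric((dx + dy) < 1.5 && max(dx, dy) < 1.5 &&
                          min(dx, dy) < 0.5),
      queen = as.numeric(max(dx, dy) < 1.5),
      distance_band = as.numeric({
        dist <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        dist > 0 && dist <= d
      }))
  }
  W
}

# Exhaustive Fisher-Jenks: minimal within-class SSD over all contiguous
# partitions of the sorted values into k groups.
bruteJenksSSD <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssdOf <- function(idx) sum((v[idx] - mean(v[idx]))^2)
  if (k == 1) return(ssdOf(seq_len(n)))
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (col in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, col], n)
    ssd <- 0
    for (g in seq_len(k)) ssd <- ssd + ssdOf((cuts[g] + 1):cuts[g + 1])
    best <- min(best, ssd)
  }
  best
}

# A small aligned random landscape + matching population used across tests.
makeTestLandscape <- function(seed = 42, nrow = 12, ncol = 12) {
  cfg <- hdindex::scenarioConfig(seed = seed, nrow = nrow, ncol = ncol,
                                 periods = c("p1", "p2"),
                                 clusteringStrength = 1)
  lu <- hdindex::generateLandUse(cfg)
  pop <- hdindex::generatePopulation(lu, cfg)
  list(cfg = cfg, lu = lu, pop = pop)
}
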