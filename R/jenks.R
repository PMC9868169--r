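#' Fisher-Jenks natural-breaks classification
#'
#' Optimal 1-D classification of a multiset of values into \code{k} classes
#' minimizing the total within-class sum of squared deviations, computed by
#' the Fisher dynamic program on distinct values with multiplicities (exact
#' for the multiset, deterministic, ties never split across classes). For
#' large inputs the values are first reduced to \code{nbins} quantile bins
#' (bin means with counts) before the dynamic program; pass
#' \code{exact = TRUE} to force the full computation.
#'
#' @param values numeric vector (NAs dropped); needs at least \code{k}
#'   distinct values.
#' @param k number of classes, >= 1.
#' @param exact force the exact DP regardless of input size.
#' @param nbins quantile-bin count for the approximate path (default 2048).
#' @return A \linkS4class{BreaksSpec} with boundaries \code{c(min, class
#'   maxima)} and labels \code{1:k}.
#' @examples
#' jenksBreaks(c(1, 2, 3, 4, 5, 6), 2)  # splits {1,2,3} | {4,5,6}
#' @export
jenksBreaks <- function(values, k, exact = FALSE, nbins = 2048L) {
  values <- values[!is.na(values)]
  if (k < 1L) stop("k must be >= 1")
  u <- sort(unique(values))
  if (length(u) < k)
    stop("degenerate-input error: ", length(u), " distinct values < k = ", k)
  w <- as.numeric(table(match(values, u)))  # multiplicities in sorted order
  if (!exact && length(u) > nbins) {
    qs <- stats::quantile(values, probs = seq(0, 1, length.out = nbins + 1L),
                          names = FALSE, type = 7)
    bin <- findInterval(values, unique(qs), rightmost.closed = TRUE)
    u <- as.numeric(tapply(values, bin, mean))
    w <- as.numeric(tapply(values, bin, length))
    o <- order(u); u <- u[o]; w <- w[o]
    if (length(u) < k)
      stop("degenerate-input error after binning; pass exact = TRUE")
  }
  part <- .fisherJenksDP(u, w, k)
  boundaries <- c(u[1], u[part$ends])
  new("BreaksSpec", boundaries = boundaries, labels = seq_len(k),
      method = "jenks")
}

# DP over distinct values u with weights w. Returns the end index of each
# class (in u) and the optimal total within-class SSD.
.fisherJenksDP <- function(u, w, k) {
  m <- length(u)
  S0 <- cumsum(w); S1 <- cumsum(w * u); S2 <- cumsum(w * u^2)
  z0 <- c(0, S0); z1 <- c(0, S1); z2 <- c(0, S2)
  ssd <- function(j, i) {  # vectorized over j: class covering u[j..i]
    n <- z0[i + 1] - z0[j]
    s <- z1[i + 1] - z1[j]
    q <- z2[i + 1] - z2[j]
    q - s^2 / n
  }
  D <- matrix(Inf, k, m)
  back <- matrix(0L, k, m)
  D[1, ] <- ssd(1L, seq_len(m))
  back[1, ] <- 1L
  if (k > 1) for (c in 2:k) {
    for (i in c:m) {
      j <- c:i  # class c starts at u[j]
      cand <- D[c - 1, j - 1] + ssd(j, i)
      best <- which.min(cand)
      D[c, i] <- cand[best]
      back[c, i] <- j[best]
    }
  }
  ends <- integer(k)
  i <- m
  for (c in k:1) {
    ends[c] <- i
    i <- back[c, i] - 1L
  }
  list(ends = ends, ssd = D[k, m])
}

#' Total within-class SSD of a partition defined by breaks
#'
#' @param values numeric vector.
#' @param breaks a \linkS4class{BreaksSpec}.
#' @return numeric scalar.
#' @export
withinClassSSD <- function(values, breaks) {
  values <- values[!is.na(values)]
  cls <- classifyByBreaks(values, breaks)
  sum(tapply(values, cls, function(v) sum((v - mean(v))^2)))
}

#' Goodness of variance fit of a classification
#'
#' \code{1 - SSD_within / SSD_total}; 1 is a perfect fit.
#'
#' @inheritParams withinClassSSD
#' @return numeric in [0, 1].
#' @export
goodnessOfVarianceFit <- function(values, breaks) {
  values <- values[!is.na(values)]
  tot <- sum((values - mean(values))^2)
  if (tot == 0) return(1)
  1 - withinClassSSD(values, breaks) / tot
}

#' Equal-interval breaks
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes.
#' @return A \linkS4class{BreaksSpec}.
#' @export
equalIntervalBreaks <- function(values, k) {
  values <- values[!is.na(values)]
  lo <- min(values); hi <- max(values)
  if (hi == lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  new("BreaksSpec", boundaries = seq(lo, hi, length.out = k + 1L),
      labels = seq_len(k), method = "equal_interval")
}

#' Class membership under a BreaksSpec
#'
#' Bins are half-open on the right, (b_{i-1}, b_i], with the first closed at
#' b_0; a value exactly on an interior boundary goes to the lower class.
#' Values outside [b_0, b_k] are clamped into the terminal classes.
#'
#' @param values numeric vector (NA passes through).
#' @param breaks a \linkS4class{BreaksSpec}.
#' @return integer class labels.
#' @export
classifyByBreaks <- function(values, breaks) {
  b <- breaks@boundaries
  k <- length(breaks@labels)
  inner <- b[-c(1L, k + 1L)]
  idx <- findInterval(values, inner, left.open = TRUE) + 1L
  idx <- pmin(pmax(idx, 1L), k)
  breaks@labels[idx]
}

#' Persist breaks as a JSON sidecar
#'
#' Scoring is reproducible across runs when the pooled breaks are saved next
#' to the score rasters and reloaded.
#'
#' @param breaks a \linkS4class{BreaksSpec}.
#' @param path JSON file path.
#' @return \code{writeBreaks}: \code{path} invisibly; \code{readBreaks}: a
#'   \linkS4class{BreaksSpec}.
#' @export
writeBreaks <- function(breaks, path) {
  jsonlite::write_json(list(boundaries = breaks@boundaries,
                            labels = breaks@labels,
                            method = breaks@method),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeBreaks
#' @export
readBreaks <- function(path) {
  x <- jsonlite::fromJSON(path)
  new("BreaksSpec", boundaries = as.numeric(x$boundaries),
      labels = as.integer(x$labels), method = as.character(x$method))
}
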