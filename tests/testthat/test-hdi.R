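test_that("Jenks splits {1..6} into {1,2,3}|{4,5,6} and handles k = n", {
  b <- jenksBreaks(1:6, 2)
  expect_equal(b@boundaries, c(1, 3, 6))
  expect_equal(classifyByBreaks(1:6, b), c(1L, 1L, 1L, 2L, 2L, 2L))
  bn <- jenksBreaks(c(2, 5, 9), 3)
  expect_equal(bn@boundaries, c(2, 2, 5, 9))
  expect_equal(withinClassSSD(c(2, 5, 9), bn), 0)
  expect_error(jenksBreaks(c(1, 1, 2), 3), "degenerate-input")
})

test_that("Jenks DP equals exhaustive partition enumeration", {
  withSeed(101, {
    for (rep in 1:40) {
      n <- sample(4:12, 1)
      k <- sample(2:min(4, n - 1), 1)
      v <- runif(n, 0, 100)
      b <- jenksBreaks(v, k, exact = TRUE)
      expect_equal(withinClassSSD(v, b), bruteJenksSSD(v, k),
                   tolerance = 1e-9)
    }
  })
})

test_that("Jenks never fits variance worse than equal intervals", {
  withSeed(55, {
    for (rep in 1:20) {
      v <- c(runif(30, 0, 10), runif(10, 50, 60))
      k <- sample(3:6, 1)
      expect_gte(goodnessOfVarianceFit(v, jenksBreaks(v, k)) + 1e-12,
                 goodnessOfVarianceFit(v, equalIntervalBreaks(v, k)))
    }
  })
})

test_that("binned Jenks matches exact Jenks on moderate data", {
  withSeed(66, {
    v <- rnorm(5000, 50, 10)
    be <- jenksBreaks(v, 5, exact = TRUE)
    bb <- jenksBreaks(v, 5, nbins = 512)
    # same classification for nearly all cells
    agree <- mean(classifyByBreaks(v, be) == classifyByBreaks(v, bb))
    expect_gt(agree, 0.98)
  })
})

test_that("boundary ties classify into the lower class", {
  b <- new("BreaksSpec", boundaries = c(0, 2, 4), labels = 1:2,
           method = "jenks")
  expect_equal(classifyByBreaks(c(0, 2, 2.0001, 4), b), c(1L, 1L, 2L, 2L))
})

test_that("breaks survive a JSON sidecar round trip", {
  b <- jenksBreaks(runif(50), 4)
  f <- tempfile(fileext = ".json")
  writeBreaks(b, f)
  b2 <- readBreaks(f)
  expect_equal(b2@boundaries, b@boundaries)
  expect_identical(b2@labels, b@labels)
})

test_that("standardization pools periods, zeroes stay zero, scores 1..k", {
  z <- valueGrid(matrix(0, 4, 4))
  out <- standardizeScores(list(z, z))
  expect_equal(gridValues(out$scores[[1]]), matrix(0, 4, 4))

  v <- valueGrid(matrix(c(1:10) * 1.5, 2, 5))
  out2 <- standardizeScores(v, k = 10)
  expect_setequal(as.vector(gridValues(out2$scores)), 1:10)
  expect_equal(rank(as.vector(gridValues(out2$scores))),
               rank(as.vector(gridValues(v))))

  withSeed(12, {
    a <- valueGrid(matrix(runif(100, 1, 50), 10, 10))
    out3 <- standardizeScores(list(a, a), k = 10)
    expect_identical(gridValues(out3$scores[[1]]),
                     gridValues(out3$scores[[2]]))
  })
})

test_that("standardization is monotone within one pooled scaling", {
  withSeed(19, {
    a <- valueGrid(matrix(runif(144, 0, 9), 12, 12))
    b <- valueGrid(matrix(runif(144, 0, 9), 12, 12))
    out <- standardizeScores(list(a, b), k = 10)
    va <- c(gridValues(a), gridValues(b))
    sa <- c(gridValues(out$scores[[1]]), gridValues(out$scores[[2]]))
    o <- order(va)
    expect_true(all(diff(sa[o]) >= 0 | diff(va[o]) == 0))
    # same raw value -> same score across periods, by construction of o
  })
})

test_that("degenerate pooled distributions fall back to equal intervals", {
  g <- valueGrid(matrix(c(0, 1, 1, 2), 2, 2))
  expect_warning(out <- standardizeScores(g, k = 10), "equal-interval")
  expect_equal(out$breaks@method, "equal_interval")
  expect_equal(gridValues(out$scores)[1, 1], 0)
})

test_that("layer sums are weighted, aligned, and nodata-propagating", {
  a <- valueGrid(matrix(3, 2, 2)); b <- valueGrid(matrix(4, 2, 2))
  expect_equal(gridValues(sumLayers(list(a))), matrix(3, 2, 2))
  expect_equal(gridValues(sumLayers(list(a, b))), matrix(7, 2, 2))
  withSeed(7, {
    l <- lapply(1:3, function(i) valueGrid(matrix(rnorm(4), 2, 2)))
    w <- c(1, 0.5, 2)
    want <- w[1] * gridValues(l[[1]]) + w[2] * gridValues(l[[2]]) +
      w[3] * gridValues(l[[3]])
    expect_equal(gridValues(sumLayers(l, w)), want)
  })
  expect_error(sumLayers(list(a, valueGrid(matrix(0, 3, 3)))), "alignment")
  expect_error(sumLayers(list(a, b), weights = 1), "length")
})

test_that("HDI combination validates component ranges and sums", {
  z <- function(x, n = 2) valueGrid(matrix(x, n, n))
  h0 <- combineHdi(z(0), z(0), z(0))
  expect_equal(hdiValues(h0), matrix(0, 2, 2))
  hmax <- combineHdi(z(10), z(20), z(30))
  expect_equal(hdiValues(hmax), matrix(60, 2, 2))
  withSeed(3, {
    l <- valueGrid(matrix(runif(4, 0, 10), 2, 2))
    r <- valueGrid(matrix(runif(4, 0, 20), 2, 2))
    p <- valueGrid(matrix(runif(4, 0, 30), 2, 2))
    h <- combineHdi(l, r, p)
    expect_equal(hdiValues(h),
                 gridValues(l) + gridValues(r) + gridValues(p))
    expect_equal(gridValues(componentLayer(h, "rci")), gridValues(r))
  })
  expect_error(combineHdi(z(11), z(0), z(0)), "lni")
  expect_error(combineHdi(z(0), z(21), z(0)), "rci")
})

test_that("level classification reproduces the 0-6 .. 55-60 table", {
  hdi <- valueGrid(matrix(as.numeric(0:60), 1, 61))
  lev <- levelValues(classifyLevels(hdi))
  expect_equal(lev[1, 1:7], rep(1L, 7))            # 0..6 -> I
  expect_equal(lev[1, 8:13], rep(2L, 6))           # 7..12 -> II
  expect_equal(lev[1, 26:31], rep(5L, 6))          # 25..30 -> V
  expect_equal(lev[1, 56:61], rep(10L, 6))         # 55..60 -> X
  expect_equal(as.vector(lev), pmax(1L, as.integer(ceiling((0:60) / 6))))
  expect_error(classifyLevels(valueGrid(matrix(61, 1, 1))), "range error")
  # composition with combineHdi is total and lands in I..X
  withSeed(31, {
    l <- valueGrid(matrix(runif(64, 0, 10), 8, 8))
    r <- valueGrid(matrix(runif(64, 0, 20), 8, 8))
    p <- valueGrid(matrix(runif(64, 0, 30), 8, 8))
    lv <- levelValues(classifyLevels(combineHdi(l, r, p)))
    expect_true(all(lv %in% 1:10))
  })
})

test_that("level tabulation percentages count cells and sum to 100", {
  u <- new("LevelGrid", spec = gridSpec(4, 4, 1000),
           levels = matrix(4L, 4, 4))
  t1 <- tabulateLevels(u)
  expect_equal(t1$IV, 100)
  expect_equal(sum(unlist(t1[levelLabels()])), 100)
  half <- matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4)
  t2 <- tabulateLevels(new("LevelGrid", spec = gridSpec(4, 4, 1000),
                           levels = half))
  expect_equal(c(t2$I, t2$II), c(50, 50))
  withSeed(44, {
    lv <- matrix(sample(1:10, 400, TRUE), 20, 20)
    lv[sample(400, 20)] <- NA
    tg <- new("LevelGrid", spec = gridSpec(20, 20, 1000), levels = lv)
    t3 <- tabulateLevels(tg)
    counts <- vapply(1:10, function(k) sum(lv == k, na.rm = TRUE), 0L)
    expect_equal(as.numeric(unlist(t3[levelLabels()])),
                 100 * counts / sum(counts))
    expect_equal(sum(unlist(t3[levelLabels()])), 100, tolerance = 1e-12)
    # by zone
    zm <- valueGrid(matrix(rep(1:2, each = 200), 20, 20),
                    spec = gridSpec(20, 20, 1000))
    t4 <- tabulateLevels(tg, zones = zm)
    expect_equal(nrow(t4), 2L)
    for (i in 1:2)
      expect_equal(sum(unlist(t4[i, levelLabels()])), 100,
                   tolerance = 1e-12)
  })
})
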