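test_that("contiguity weights enumerate the expected neighbors", {
  s2 <- gridSpec(2, 2, 1000)
  wr <- buildWeights(s2, scheme = "rook")
  expect_equal(neighborCounts(wr), rep(2L, 4))
  s3 <- gridSpec(3, 3, 1000)
  wq <- buildWeights(s3, scheme = "queen")
  centerRow <- which(wq@cells == 5)  # linear index 5 = center of 3x3
  expect_equal(neighborCounts(wq)[centerRow], 8L)
  expect_error(buildWeights(s3, scheme = "distance_band", d = 500),
               "empty-neighborhood")
})

test_that("weights match a brute-force pairwise scan on random masks", {
  withSeed(71, {
    spec <- gridSpec(7, 6, 1000)
    mask <- matrix(runif(42) > 0.25, 7, 6)
    mask[1, 1] <- TRUE; mask[7, 6] <- TRUE
    for (sch in c("rook", "queen")) {
      w <- buildWeights(spec, mask, scheme = sch)
      B <- bruteNeighborMatrix(spec, mask, sch)
      expect_equal(as.matrix(w@W), B, ignore_attr = TRUE)
    }
    w <- buildWeights(spec, mask, scheme = "distance_band", d = 2200)
    B <- bruteNeighborMatrix(spec, mask, "distance_band", d = 2200)
    expect_equal(as.matrix(w@W), B, ignore_attr = TRUE)
    expect_true(Matrix::isSymmetric(w@W))
    expect_true(all(Matrix::diag(w@W) == 0))
  })
})

test_that("Moran's I: checkerboard is exactly -1, blocks are positive", {
  m <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  g <- valueGrid(m)
  w <- buildWeights(gridSpecOf(g), scheme = "rook")
  expect_identical(moransI(g, w), -1)
  blocks <- matrix(c(rep(1, 18), rep(5, 18)), 6, 6)
  expect_gt(moransI(valueGrid(blocks), w), 0)
  expect_error(moransI(valueGrid(matrix(2, 6, 6)), w), "degenerate-field")
})

test_that("Moran's I equals the brute-force double sum", {
  withSeed(88, {
    for (rep in 1:3) {
      spec <- gridSpec(5, 5, 1000)
      v <- matrix(rnorm(25), 5, 5)
      for (sch in c("rook", "queen")) {
        w <- buildWeights(spec, scheme = sch)
        got <- moransI(valueGrid(v, spec = spec), w)
        want <- bruteMoranI(v[w@cells], bruteNeighborMatrix(
          spec, matrix(TRUE, 5, 5), sch))
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("Moran z-test: gradient fields are significant, normality moments sane", {
  grad <- outer(1:10, 1:10, `+`)
  g <- valueGrid(grad)
  w <- buildWeights(gridSpecOf(g), scheme = "queen")
  zt <- moranZ(g, w)
  expect_equal(zt$expectation, -1 / 99)
  expect_gt(zt$Z, 2.576)
  expect_lt(zt$p, 0.01)
  # permutation route agrees in direction and magnitude
  zp <- moranZ(g, w, method = "permutation", nperm = 199, seed = 5)
  expect_gt(zp$Z, 2.576)
  expect_lt(zp$p, 0.02)
})

test_that("weighted centroid follows the mass and its invariances", {
  spec <- gridSpec(4, 4, 1000, originX = 0, originY = 4000)
  uni <- valueGrid(matrix(2, 4, 4), spec = spec)
  expect_equal(weightedCentroid(uni), c(X = 2000, Y = 2000))
  single <- matrix(0, 4, 4); single[2, 3] <- 5
  expect_equal(weightedCentroid(valueGrid(single, spec = spec)),
               c(X = 2500, Y = 2500))
  two <- valueGrid(matrix(c(1, 1, 3, 3), 2, 2),
                   spec = gridSpec(2, 2, 1000, originX = 0, originY = 2000))
  # columns weigh 1 and 3: X = (500*2 + 1500*6)/8
  expect_equal(weightedCentroid(two)[["X"]], (500 * 2 + 1500 * 6) / 8)
  expect_equal(weightedCentroid(two)[["Y"]], 1000)
  withSeed(15, {
    v <- matrix(runif(16), 4, 4)
    g1 <- valueGrid(v, spec = spec)
    c1 <- weightedCentroid(g1)
    expect_equal(weightedCentroid(valueGrid(7.3 * v, spec = spec)), c1)
    shifted <- gridSpec(4, 4, 1000, originX = 100, originY = 4200)
    c2 <- weightedCentroid(valueGrid(v, spec = shifted))
    expect_equal(c2, c1 + c(X = 100, Y = 200))
  })
  expect_error(weightedCentroid(valueGrid(matrix(0, 2, 2))),
               "undefined-centroid")
})

test_that("centroid track kinematics: displacement, bearing, speed", {
  ct <- centroidTrack(data.frame(period = c("a", "b"),
                                 X = c(0, 300), Y = c(0, 400)), 2)
  seg <- trackSegments(ct)
  expect_equal(seg$displacement, 500)
  expect_equal(seg$bearing, atan2(300, 400) * 180 / pi)
  expect_equal(seg$speed, 250)
  still <- centroidTrack(data.frame(period = c("a", "b"),
                                    X = c(1, 1), Y = c(2, 2)), 5)
  expect_equal(trackSegments(still)$displacement, 0)
  expect_equal(trackSegments(still)$speed, 0)
  expect_error(centroidTrack(data.frame(period = c("a", "b"),
                                        X = 0:1, Y = 0:1), 0),
               "non-positive interval")
  # cardinal binning
  d <- 1 / sqrt(2)
  ct8 <- centroidTrack(data.frame(period = letters[1:5],
                                  X = c(0, 0, 1, 1 + d, 1 + d),
                                  Y = c(0, 1, 1, 1 - d, 2 - d)),
                       rep(1, 4))
  expect_equal(trackSegments(ct8)$direction, c("N", "E", "SE", "N"))
})

test_that("Gi* equals 1 under full weights and satisfies the sum identity", {
  withSeed(23, {
    spec <- gridSpec(5, 5, 1000)
    v <- matrix(runif(25, 1, 10), 5, 5)
    g <- valueGrid(v, spec = spec)
    full <- getisOrdGiStar(g, d = 1e9)
    expect_equal(full$giStar, matrix(1, 5, 5))
    res <- getisOrdGiStar(g, d = 2000)
    # sum_i Gi* * sum_j x_j == sum_i sum_j W_ij(d) x_j (self included)
    B <- bruteNeighborMatrix(spec, matrix(TRUE, 5, 5), "distance_band",
                             d = 2000)
    diag(B) <- 1
    lhs <- sum(res$giStar) * sum(v)
    rhs <- sum(B %*% v[res$weights@cells])
    expect_equal(lhs, rhs, tolerance = 1e-9)
  })
})

test_that("constant fields yield z = 0 everywhere by convention", {
  g <- valueGrid(matrix(3, 4, 4))
  expect_message(res <- getisOrdGiStar(g), "constant field")
  expect_equal(res$z, matrix(0, 4, 4))
  expect_true(all(res$category == "not_significant"))
  expect_error(getisOrdGiStar(valueGrid(matrix(0, 3, 3))), "zero-sum")
})

test_that("Gi* z-scores average near zero on exchangeable fields", {
  withSeed(99, {
    g <- valueGrid(matrix(rlnorm(2500), 50, 50))
    res <- getisOrdGiStar(g)
    expect_lt(abs(mean(res$z)), 0.1)
  })
})

test_that("planted clusters are recovered as hot spots", {
  withSeed(37, {
    spec <- gridSpec(50, 50, 1000)
    bg <- valueGrid(matrix(rnorm(2500, 50, 5), 50, 50), spec = spec)
    pl <- plantClusters(bg, list(list(x = 25000, y = 25000,
                                      radius = 6000, effect = 3)))
    res <- getisOrdGiStar(pl$grid)
    frac <- mean(res$category[pl$mask] %in% c("hot95", "hot99"))
    expect_gte(frac, 0.9)
    # far-away background is not flagged hot
    far <- !pl$mask & (row(pl$mask) < 10 | row(pl$mask) > 40)
    expect_lt(mean(res$category[far] %in% c("hot95", "hot99")), 0.1)
  })
})
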