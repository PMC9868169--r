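test_that("standard-coal conversion is linear and additive", {
  expect_equal(toStandardCoal(numeric(0)), 0)
  tab <- c(a = 0.7, b = 1.4)
  expect_equal(toStandardCoal(c(a = 10), tab), 7)
  withSeed(3, {
    for (i in 1:5) {
      qa <- runif(1, 0, 100); qb <- runif(1, 0, 100)
      expect_equal(toStandardCoal(c(a = qa, b = qb), tab),
                   toStandardCoal(c(a = qa), tab) +
                     toStandardCoal(c(b = qb), tab))
    }
  })
  expect_error(toStandardCoal(c(plutonium = 1), tab), "unknown carrier")
})

test_that("temporal averaging covers exactly the window", {
  expect_equal(temporalAverage(data.frame(year = 2001:2005,
                                          value = rep(4, 5)), 2001:2005), 4)
  expect_equal(temporalAverage(data.frame(year = 2016:2018,
                                          value = c(1, 2, 3)), 2016:2018), 2)
  withSeed(8, {
    v <- runif(7, 0, 10)
    s <- data.frame(year = 2000:2006, value = v)
    win <- 2001:2005
    acc <- 0
    for (y in win) acc <- acc + v[y - 1999]  # summation oracle
    expect_equal(temporalAverage(s, win), acc / 5)
  })
  expect_error(temporalAverage(data.frame(year = 2001:2004,
                                          value = 1:4), 2001:2005), "2005")
})

test_that("per-area allocation is uniform and conserves the total", {
  codes <- matrix(9L, 4, 4)
  codes[1, ] <- 1L  # 4 arable cells
  lu <- landUseGrid(codes, spec = gridSpec(4, 4, 1000))
  g <- allocatePerArea(100, lu, "arable")
  expect_equal(gridValues(g)[1, ], rep(25, 4))
  expect_equal(gridValues(g)[2, ], rep(0, 4))
  expect_equal(gridTotal(g), 100, tolerance = 1e-12)
  z <- allocatePerArea(0, lu, "arable")
  expect_equal(gridValues(z), matrix(0, 4, 4))
  expect_error(allocatePerArea(5, lu, "forest"), "allocation error")
})

test_that("explicit split fractions give equal within-class densities and conserve", {
  withSeed(21, {
    ls <- makeTestLandscape()
    g <- allocatePerArea(500, ls$lu, c("forest", "grassland"),
                         split = c(forest = 0.7, grassland = 0.3))
    v <- gridValues(g)
    fm <- classMask(ls$lu, "forest"); gm <- classMask(ls$lu, "grassland")
    expect_equal(length(unique(v[fm])), 1L)
    expect_equal(length(unique(v[gm])), 1L)
    expect_equal(sum(v[fm]) * cellAreaKm2(gridSpecOf(g)), 350,
                 tolerance = 1e-9)
    expect_equal(gridTotal(g), 500, tolerance = 1e-9)
  })
})

test_that("residential consumption is a cellwise density-rate product", {
  codes <- matrix(9L, 3, 3)
  codes[1, 1] <- 6L  # urban
  codes[2, 2] <- 7L  # rural
  lu <- landUseGrid(codes)
  pop <- matrix(0, 3, 3)
  pop[1, 1] <- 1000
  g <- residentialConsumption(valueGrid(pop), lu,
                              list(urban = 2, rural = 1))
  expect_equal(gridValues(g)[1, 1], 2000)
  expect_equal(sum(gridValues(g)), 2000)
  zero <- residentialConsumption(valueGrid(matrix(0, 3, 3)), lu,
                                 list(urban = 2, rural = 1))
  expect_equal(gridValues(zero), matrix(0, 3, 3))
  withSeed(4, {
    ls <- makeTestLandscape()
    rates <- list(urban = 1.7, rural = 0.4)
    g2 <- residentialConsumption(ls$pop, ls$lu, rates)
    # hand-computed cellwise oracle
    want <- matrix(0, 12, 12)
    pv <- gridValues(ls$pop)
    want[classMask(ls$lu, "urban")] <- pv[classMask(ls$lu, "urban")] * 1.7
    want[classMask(ls$lu, "rural")] <- pv[classMask(ls$lu, "rural")] * 0.4
    expect_equal(gridValues(g2), want)
  })
  expect_error(residentialConsumption(valueGrid(matrix(-1, 3, 3)), lu,
                                      list(urban = 1, rural = 1)),
               "negative")
})

test_that("transport energy spreads over built-up classes and conserves", {
  onlyUrban <- landUseGrid(matrix(6L, 2, 2))
  g <- transportEnergySpread(40, onlyUrban)
  expect_equal(gridTotal(g), 40, tolerance = 1e-12)
  codes <- matrix(c(6L, 7L, 8L, 9L), 2, 2)
  lu <- landUseGrid(codes)
  g2 <- transportEnergySpread(30, lu)
  v <- gridValues(g2)
  expect_equal(v[1, 1], v[2, 1])  # equal areas -> equal densities
  expect_equal(v[1, 1], v[1, 2])
  expect_equal(v[2, 2], 0)
  withSeed(13, {
    ls <- makeTestLandscape()
    expect_equal(gridTotal(transportEnergySpread(123.4, ls$lu)), 123.4,
                 tolerance = 1e-9 * 123.4)
  })
})

test_that("consumption surfaces conserve sector totals plus residential use", {
  ls <- makeTestLandscape(seed = 31)
  stats <- generateStatistics(ls$cfg, "energy", noiseSd = 0)
  rates <- list(urban = 1e-4, rural = 4e-5)
  surf <- suppressMessages(
    buildConsumptionSurface(stats, "p1", ls$lu, ls$pop, rates))
  res <- residentialConsumption(ls$pop, ls$lu, rates)
  allocated <- stats[stats$period == "p1" &
                       !stats$sector %in% c("urban_residents",
                                            "rural_residents"), ]
  want <- sum(allocated$quantity) + gridTotal(res)
  expect_equal(gridTotal(surf), want, tolerance = 1e-9 * want)
})

test_that("single-sector statistics reduce to plain allocation", {
  ls <- makeTestLandscape(seed = 17)
  stats <- data.frame(period = "p1", region = "r", sector = "agriculture",
                      quantity = 88, units = "u")
  surf <- buildConsumptionSurface(stats, "p1", ls$lu)
  direct <- allocatePerArea(88, ls$lu, "arable")
  expect_equal(gridValues(surf), gridValues(direct))
  zeroStats <- stats; zeroStats$quantity <- 0
  z <- buildConsumptionSurface(zeroStats, "p1", ls$lu)
  expect_true(all(gridValues(z) == 0, na.rm = TRUE))
})

test_that("unmapped sectors error; ignored sectors are logged not dropped", {
  ls <- makeTestLandscape(seed = 17)
  stats <- data.frame(period = "p1", region = "r", sector = "mining",
                      quantity = 5, units = "u")
  expect_error(buildConsumptionSurface(stats, "p1", ls$lu), "mining")
  stats2 <- data.frame(period = "p1", region = "r",
                       sector = c("agriculture", "other"),
                       quantity = c(10, 5), units = "u")
  expect_message(buildConsumptionSurface(stats2, "p1", ls$lu), "ignore")
})

test_that("increasing a sector total weakly increases the surface", {
  ls <- makeTestLandscape(seed = 23)
  mk <- function(q) data.frame(period = "p1", region = "r",
                               sector = c("agriculture", "industry"),
                               quantity = c(q, 20), units = "u")
  lo <- buildConsumptionSurface(mk(10), "p1", ls$lu)
  hi <- buildConsumptionSurface(mk(15), "p1", ls$lu)
  d <- gridValues(hi) - gridValues(lo)
  expect_true(all(d >= 0, na.rm = TRUE))
  expect_true(any(d > 0, na.rm = TRUE))
})

test_that("zone-wise allocation mosaics regional totals and conserves", {
  ls <- makeTestLandscape(seed = 29)
  spec <- gridSpecOf(ls$lu)
  zm <- matrix(1, 12, 12); zm[, 7:12] <- 2
  zones <- valueGrid(zm, spec = spec)
  stats <- data.frame(period = "p1",
                      region = c("west", "east"),
                      sector = "agriculture",
                      quantity = c(60, 140), units = "u")
  surf <- buildConsumptionSurface(stats, "p1", ls$lu, zones = zones,
                                  regionZones = c(west = 1, east = 2))
  west <- zonalMask(surf, zones, 1)
  east <- zonalMask(surf, zones, 2)
  expect_equal(gridTotal(west), 60, tolerance = 1e-9 * 60)
  expect_equal(gridTotal(east), 140, tolerance = 1e-9 * 140)
})
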