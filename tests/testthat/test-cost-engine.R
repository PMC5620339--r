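test_that("step times match hand-computed values", {
  g <- makeGrid(1, 2)
  dem <- flatDem(g)
  boat <- ClassRaster(g, landClassCode("boat_route"))
  # 30 m at 15 km/h
  expect_equal(edgeTime(boat, dem, defaultSpeedTable("walking"),
                        c(1, 1), c(1, 2)), 0.12)
  # grassland -> settlement rook step, walking, flat
  mix <- ClassRaster(g, matrix(landClassCode(c("grassland", "settlement")), 1))
  expect_equal(edgeTime(mix, dem, defaultSpeedTable("walking"),
                        c(1, 1), c(1, 2)),
               15 * (1 / 1.7 + 1 / 2.5) * 60 / 1000)
})

test_that("steps into barrier cells are impossible", {
  g <- makeGrid(1, 2)
  v <- matrix(landClassCode(c("grassland", "wetland")), 1)
  cr <- ClassRaster(g, v)
  expect_true(is.na(edgeTime(cr, flatDem(g), defaultSpeedTable("car"),
                             c(1, 1), c(1, 2))))
  expect_error(edgeTime(cr, flatDem(g), defaultSpeedTable("car"),
                        c(1, 1), c(1, 4)), "adjacent")
})

test_that("a one-step path costs exactly one edge time", {
  g <- makeGrid(3)
  cr <- uniformClass(g, "grassland")
  dem <- flatDem(g)
  st <- defaultSpeedTable("walking")
  surf <- accumulateTravelTime(cr, dem, st, cbind(2, 2))
  expect_equal(gridValues(surf)[2, 3],
               edgeTime(cr, dem, st, c(2, 3), c(2, 2)))
  expect_equal(gridValues(surf)[2, 2], 0)
})

test_that("multi-source surfaces are the cell-wise minimum over sources", {
  L <- randomLandscape(11)
  st <- defaultSpeedTable("motorcycle")
  s2 <- which(!matrix(gridValues(L$combined) %in% barrierCodes(), 40, 40),
              arr.ind = TRUE)[200, , drop = FALSE]
  one <- accumulateTravelTime(L$combined, L$dem, st, L$source)
  two <- accumulateTravelTime(L$combined, L$dem, st, s2)
  both <- accumulateTravelTime(L$combined, L$dem, st, rbind(L$source, s2))
  expect_equal(gridValues(both),
               pmin(gridValues(one), gridValues(two), na.rm = TRUE))
})

test_that("the engine matches the explicit-graph oracle on random landscapes", {
  for (seed in c(3, 7)) {
    L <- randomLandscape(seed, n = 25)
    for (sc in c("walking", "car")) {
      st <- defaultSpeedTable(sc)
      a <- gridValues(accumulateTravelTime(L$combined, L$dem, st, L$source))
      b <- gridValues(oracleTravelTime(L$combined, L$dem, st, L$source))
      expect_identical(is.na(a), is.na(b))
      ok <- !is.na(a)
      expect_lt(max(abs(a[ok] - b[ok]) / pmax(b[ok], 1e-12)), 1e-9)
    }
  }
})

test_that("the engine matches the oracle under 16-connectivity", {
  L <- randomLandscape(5, n = 20)
  st <- defaultSpeedTable("cycling")
  cfg <- EngineConfig(16)
  a <- gridValues(accumulateTravelTime(L$combined, L$dem, st, L$source,
                                       config = cfg))
  b <- gridValues(oracleTravelTime(L$combined, L$dem, st, L$source,
                                   config = cfg))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("walking times are direction-asymmetric on slopes", {
  g <- makeGrid(1, 10)
  cr <- uniformClass(g, "grassland")
  # constant west-east gradient
  dem <- Dem(g, matrix(seq(1000, by = 6, length.out = 10), 1))
  st <- defaultSpeedTable("walking")
  up <- gridValues(accumulateTravelTime(cr, dem, st, cbind(1, 10)))[1, 1]
  down <- gridValues(accumulateTravelTime(cr, dem, st, cbind(1, 1)))[1, 10]
  expect_gt(up, down)  # walking toward the east facility climbs
  # motorized travel is direction-symmetric on the same terrain
  stc <- defaultSpeedTable("car")
  crr <- uniformClass(g, "major_road")
  upC <- gridValues(accumulateTravelTime(crr, dem, stc, cbind(1, 10)))[1, 1]
  downC <- gridValues(accumulateTravelTime(crr, dem, stc, cbind(1, 1)))[1, 10]
  expect_equal(upC, downC)
})

test_that("adding a source never increases any travel time", {
  L <- randomLandscape(21)
  st <- defaultSpeedTable("cycling")
  base <- gridValues(accumulateTravelTime(L$combined, L$dem, st, L$source))
  pass <- which(!matrix(gridValues(L$combined) %in% barrierCodes(), 40, 40),
                arr.ind = TRUE)
  extra <- rbind(L$source, pass[50, ])
  more <- gridValues(accumulateTravelTime(L$combined, L$dem, st, extra))
  ok <- !is.na(base)
  expect_true(all(!is.na(more[ok])))
  expect_true(all(more[ok] <= base[ok] + 1e-12))
})

test_that("faster tables never increase travel times (dominance)", {
  L <- randomLandscape(31)
  tW <- gridValues(accumulateTravelTime(L$combined, L$dem,
                                        defaultSpeedTable("walking"), L$source))
  tC <- gridValues(accumulateTravelTime(L$combined, L$dem,
                                        defaultSpeedTable("car"), L$source))
  tB <- gridValues(accumulateTravelTime(L$combined, L$dem,
                                        defaultSpeedTable("cycling"), L$source))
  tM <- gridValues(accumulateTravelTime(L$combined, L$dem,
                                        defaultSpeedTable("motorcycle"), L$source))
  ok <- !is.na(tW)
  expect_true(all(tC[ok] <= tW[ok] + 1e-12))
  ok2 <- !is.na(tB)
  expect_true(all(tM[ok2] <= tB[ok2] + 1e-12))
})

test_that("grid travel respects the 8-connectivity metric bound", {
  g <- makeGrid(41)
  cr <- uniformClass(g, "grassland")
  st <- defaultSpeedTable("walking")
  surf <- gridValues(accumulateTravelTime(cr, flatDem(g), st, cbind(21, 21)))
  eps <- 1 / cos(pi / 8) - 1
  for (r in seq(1, 41, by = 4)) for (cc in seq(1, 41, by = 4)) {
    straight <- sqrt((r - 21)^2 + (cc - 21)^2) * 30 / 1000 / 1.7 * 60
    expect_gte(surf[r, cc], straight - 1e-9)
    expect_lte(surf[r, cc], straight * (1 + eps) + 1e-9)
  }
})

test_that("barriers stay unreachable and diagonal squeezes are forbidden", {
  g <- makeGrid(2)
  v <- matrix(landClassCode(c("wetland", "grassland",
                              "grassland", "wetland")), 2, 2)
  cr <- ClassRaster(g, v)  # passable cells only at (2,1) and (1,2)
  surf <- gridValues(accumulateTravelTime(cr, flatDem(g),
                                          defaultSpeedTable("car"),
                                          cbind(2, 1)))
  expect_true(is.na(surf[1, 1]))
  expect_true(is.na(surf[2, 2]))
  expect_true(is.na(surf[1, 2]))  # cannot squeeze between barrier corners
  expect_equal(surf[2, 1], 0)
})

test_that("engines reject missing or all-barrier sources", {
  g <- makeGrid(3)
  cr <- uniformClass(g, "wetland")
  expect_error(accumulateTravelTime(cr, flatDem(g),
                                    defaultSpeedTable("car"),
                                    matrix(integer(0), ncol = 2)), "source")
  expect_error(accumulateTravelTime(cr, flatDem(g),
                                    defaultSpeedTable("car"), cbind(2, 2)),
               "barrier")
})
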