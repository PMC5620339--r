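test_that("zonal counts are proportional for uniform births and conserve totals", {
  g <- GridSpec(10, 10, 30)
  z <- matrix(5L, 10, 10); z[, 1:5] <- 1L       # west half good access
  zones <- ZoneRaster(g, z)
  births <- BirthRaster(g, matrix(1, 10, 10))
  counts <- zonalBirthCounts(zones, births)
  expect_equal(unname(counts["Z0_30"]), 50)
  expect_equal(unname(counts["OVER_120"]), 50)
  expect_equal(sum(counts), 100)
  # zero births
  expect_true(all(zonalBirthCounts(zones, BirthRaster(g, matrix(0, 10, 10))) == 0))
})

test_that("cross-resolution assignment matches a brute-force per-cell loop", {
  for (seed in 1:3) {
    set.seed(seed)
    zg <- GridSpec(60, 60, 30)                  # 1800 m extent
    zones <- ZoneRaster(zg, matrix(sample(1:5, 3600, TRUE), 60, 60))
    bg <- GridSpec(18, 18, 100)                 # coarser, same origin
    bv <- matrix(stats::runif(324, 0, 5), 18, 18)
    births <- BirthRaster(bg, bv)
    counts <- zonalBirthCounts(zones, births)
    # brute force: loop every birth cell, locate its centre on the zone grid
    want <- stats::setNames(numeric(5), zoneLevels())
    for (r in 1:18) for (cc in 1:18) {
      x <- (cc - 0.5) * 100; y <- (18 - r + 0.5) * 100
      zr <- 60 - floor(y / 30); zc <- floor(x / 30) + 1
      z <- gridValues(zones)[zr, zc]
      want[z] <- want[z] + bv[r, cc]
    }
    expect_equal(counts, want)
    expect_equal(sum(counts), sum(bv))
  }
})

test_that("birth cells outside the zone grid land in the over-threshold band", {
  zg <- GridSpec(5, 5, 30)
  zones <- ZoneRaster(zg, matrix(1L, 5, 5))
  bg <- GridSpec(3, 3, 100)                     # extends past the 150 m zone grid
  births <- BirthRaster(bg, matrix(1, 3, 3))
  expect_warning(counts <- zonalBirthCounts(zones, births), "outside")
  expect_equal(sum(counts), 9)
  expect_gt(counts["OVER_120"], 0)
})

test_that("per-zone proportions normalize and are scale invariant", {
  counts <- c(Z0_30 = 10, Z31_60 = 0, Z61_90 = 0, Z91_120 = 0, OVER_120 = 90)
  p <- proportionPerZone(counts)
  expect_equal(unname(p[c("Z0_30", "OVER_120")]), c(0.10, 0.90))
  expect_equal(sum(p), 1)
  expect_equal(proportionPerZone(counts * 7.3), p)
  expect_equal(unname(proportionPerZone(c(Z0_30 = 5))["Z0_30"]), 1)
  expect_error(proportionPerZone(c(Z0_30 = 0)), "positive")
})

test_that("per-council poor access matches hand-computed fractions", {
  g <- GridSpec(4, 4, 30)
  minutes <- matrix(200, 4, 4); minutes[, 1:2] <- 60   # west good, east poor
  surf <- TravelTimeSurface(g, minutes, "walking")
  lab <- matrix(2L, 4, 4); lab[1:2, ] <- 1L            # north / south councils
  units <- new("AdminUnits", grid = g, values = lab,
               unitNames = c("north", "south"), polygons = NULL)
  bv <- matrix(0, 4, 4)
  bv[1, 1] <- 3; bv[1, 4] <- 1    # north: 3 good, 1 poor -> 0.25
  bv[4, 3] <- 2; bv[4, 4] <- 2    # south: all poor -> 1
  births <- BirthRaster(g, bv)
  out <- poorAccessByUnit(surf, births, units)
  expect_equal(out, c(north = 0.25, south = 1))
  # council fully inside the catchment
  bv2 <- matrix(0, 4, 4); bv2[3, 1] <- 5
  expect_equal(unname(poorAccessByUnit(surf, BirthRaster(g, bv2),
                                       units)["south"]), 0)
  # council with no births is missing, not zero
  expect_true(is.na(poorAccessByUnit(surf, BirthRaster(g, bv2),
                                     units)["north"]))
})

test_that("total-births estimation is the plain product formula", {
  demo <- demographicParams(470000, 1.0, 0.2)
  expect_equal(estimateTotalBirths(0, demo), 0)
  expect_equal(estimateTotalBirths(1, demo), 470000 * 1.0 * 0.2)
  expect_equal(estimateTotalBirths(0.35, demo), 470000 * 0.2 * 0.35)
  expect_error(estimateTotalBirths(1.2, demo), "0, 1")
  expect_error(demographicParams(-1, 1, 1), "positive")
})

# A corridor landscape for upgrade-ranking: existing facility in the west,
# a birth cluster in the far east beyond 2 h walking, candidates between.
plantedWorld <- function() {
  g <- GridSpec(40, 160, 30)
  cmb <- ClassRaster(g, landClassCode("grassland"))
  dem <- flatDem(g)
  births <- BirthRaster(g, matrix(0, 40, 160))
  bv <- gridValues(births)
  bv[18:22, 150:155] <- 10                     # cluster: 300 births
  births <- BirthRaster(g, bv)
  existing <- data.frame(id = "E1", x = 5 * 30 - 15, y = 20 * 30 - 15)
  list(g = g, cmb = cmb, dem = dem, births = births, existing = existing)
}

test_that("a candidate beside an uncovered cluster ranks first with ~full gain", {
  w <- plantedWorld()
  candidates <- data.frame(
    id = c("near_cluster", "redundant"),
    x = c(152 * 30 - 15, 6 * 30 - 15),
    y = c(20 * 30 - 15, 20 * 30 - 15))
  rk <- rankUpgradeCandidates(candidates, w$existing, w$cmb, w$dem,
                              defaultSpeedTable("walking"), w$births)
  expect_equal(rk$id[1], "near_cluster")
  expect_equal(rk$gain_births[1], 300, tolerance = 0.01)
  # a candidate whose catchment is contained in the existing one gains 0
  expect_equal(rk$gain_births[rk$id == "redundant"], 0)
  expect_true(all(rk$gain_births >= 0))
})

test_that("greedy selection has non-increasing gains", {
  w <- plantedWorld()
  bv <- gridValues(w$births)
  bv[5:8, 80:83] <- 2                          # a second, smaller cluster
  births <- BirthRaster(w$g, bv)
  candidates <- data.frame(
    id = c("c_east", "c_mid", "c_dup"),
    x = c(152, 81, 150) * 30 - 15,
    y = c(20, 34, 20) * 30 - 15)
  rk <- rankUpgradeCandidates(candidates, w$existing, w$cmb, w$dem,
                              defaultSpeedTable("walking"), births,
                              k = 3, greedy = TRUE)
  expect_equal(nrow(rk), 3L)
  expect_true(all(diff(rk$gain_births) <= 1e-9))
  expect_true(all(rk$gain_births >= 0))
  expect_error(rankUpgradeCandidates(w$existing, w$existing, w$cmb, w$dem,
                                     defaultSpeedTable("walking"), births),
               "disjoint")
})
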