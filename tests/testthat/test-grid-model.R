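test_that("polyline rasterization burns cells within half a cell of the line", {
  g <- makeGrid(5)
  # horizontal line along the middle row's centres
  road <- VectorLayer("polyline", list(list(
    coords = cbind(c(0, 150), c(75, 75)), class = "major_road")))
  m <- gridValues(rasterizeLayer(road, g))
  expect_identical(which(!is.na(m), arr.ind = TRUE),
                   cbind(row = rep(3L, 5), col = 1:5))
  expect_true(all(m[3, ] == landClassCode("major_road")))
})

test_that("empty layers rasterize to all-nodata masks", {
  g <- makeGrid(4)
  m <- rasterizeLayer(VectorLayer("polyline", list()), g,
                      landClassCode("major_road"))
  expect_true(all(is.na(gridValues(m))))
})

test_that("diagonal rasterization agrees with a brute-force distance check", {
  g <- makeGrid(4)
  p1 <- c(0, 0); p2 <- c(120, 120)
  line <- VectorLayer("polyline", list(list(coords = rbind(p1, p2),
                                            class = "secondary_road")))
  got <- !is.na(gridValues(rasterizeLayer(line, g)))
  # independent exhaustive check over all 16 cell centres
  want <- matrix(FALSE, 4, 4)
  for (r in 1:4) for (cc in 1:4) {
    ctr <- c(g@originX + (cc - 0.5) * 30, g@originY + (4 - r + 0.5) * 30)
    v <- p2 - p1
    t <- max(0, min(1, sum((ctr - p1) * v) / sum(v * v)))
    want[r, cc] <- sqrt(sum((ctr - (p1 + t * v))^2)) <= 15
  }
  expect_identical(got, want)
})

test_that("rasterization agrees with the exhaustive test on random polylines", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:20, 1)
    g <- makeGrid(n)
    pts <- matrix(stats::runif(6, 0, n * 30), ncol = 2)
    line <- VectorLayer("polyline", list(list(coords = pts,
                                              class = "local_road_all")))
    got <- !is.na(gridValues(rasterizeLayer(line, g)))
    want <- matrix(FALSE, n, n)
    for (r in seq_len(n)) for (cc in seq_len(n)) {
      ctr <- c((cc - 0.5) * 30, (n - r + 0.5) * 30)
      dmin <- Inf
      for (i in 1:2) {
        p1 <- pts[i, ]; v <- pts[i + 1, ] - p1
        t <- max(0, min(1, sum((ctr - p1) * v) / sum(v * v)))
        dmin <- min(dmin, sqrt(sum((ctr - (p1 + t * v))^2)))
      }
      want[r, cc] <- dmin <= 15
    }
    expect_identical(got, want)
  }
})

test_that("polygon rasterization codes cells whose centres fall inside", {
  g <- makeGrid(6)
  sq <- VectorLayer("polygon", list(list(
    coords = cbind(c(30, 150, 150, 30), c(30, 30, 150, 150)),
    class = "settlement")))
  m <- gridValues(rasterizeLayer(sq, g))
  inside <- !is.na(m)
  expect_equal(sum(inside), 16)            # a 4 x 4 block of centres
  expect_true(all(which(inside, arr.ind = TRUE)[, "row"] %in% 2:5))
})

test_that("combined land cover burns rivers, then roads, then boat routes", {
  g <- makeGrid(5)
  base <- uniformClass(g, "grassland")
  river <- VectorLayer("polyline", list(list(
    coords = cbind(c(0, 150), c(75, 75)), class = "river_barrier")))
  road <- VectorLayer("polyline", list(list(
    coords = cbind(c(75, 75), c(0, 150)), class = "major_road")))
  cmb <- buildCombinedLandcover(base, rivers = river, roads = road)
  v <- gridValues(cmb)
  # the crossing cell is passable road, not river: bridge semantics
  expect_equal(v[3, 3], landClassCode("major_road"))
  expect_equal(v[3, 1], landClassCode("river_barrier"))
  expect_equal(v[1, 3], landClassCode("major_road"))
  expect_false(anyNA(v))
})

test_that("combining with no overlay layers is the identity", {
  g <- makeGrid(4)
  base <- uniformClass(g, "cropland")
  expect_identical(gridValues(buildCombinedLandcover(base)),
                   gridValues(base))
})

test_that("boat routes burn over the base cover", {
  g <- makeGrid(5)
  base <- uniformClass(g, "cropland")
  boat <- VectorLayer("polyline", list(list(
    coords = cbind(c(0, 150), c(15, 15)), class = "boat_route")))
  v <- gridValues(buildCombinedLandcover(base, boatRoutes = boat))
  expect_true(all(v[5, ] == landClassCode("boat_route")))
  expect_true(all(v[1:4, ] == landClassCode("cropland")))
})

test_that("road cells never carry the river code regardless of geometry", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- makeGrid(15)
    rnd <- function(cls) VectorLayer("polyline", lapply(1:3, function(i)
      list(coords = matrix(stats::runif(4, 0, 450), 2), class = cls)))
    roads <- rnd("secondary_road")
    cmb <- buildCombinedLandcover(uniformClass(g, "grassland"),
                                  rivers = rnd("river_barrier"),
                                  roads = roads)
    roadMask <- !is.na(gridValues(rasterizeLayer(roads, g)))
    expect_false(any(gridValues(cmb)[roadMask] ==
                       landClassCode("river_barrier")))
  }
})

test_that("facilities snap to containing cells and off barriers", {
  g <- makeGrid(5)
  v <- matrix(landClassCode("grassland"), 5, 5)
  v[2, 2] <- landClassCode("wetland")
  v[2, 3] <- landClassCode("settlement")
  cmb <- ClassRaster(g, v)
  fac <- data.frame(id = c("a", "b"),
                    x = c(30 * 2.5, 30 * 1.6),   # cell (3,3); cell (2,2)
                    y = c(30 * 2.5, 30 * 3.4))
  src <- suppressMessages(snapFacilities(fac, cmb))
  # b sits south-east of the wetland cell centre, so the nearest passable
  # cell is the settlement cell to the east
  expect_equal(src$row, c(3L, 2L))
  expect_equal(src$col, c(3L, 3L))
})

test_that("co-located facilities share one source cell with both ids", {
  g <- makeGrid(4)
  cmb <- uniformClass(g, "settlement")
  fac <- data.frame(id = c("a", "b"), x = c(40, 50), y = c(40, 50))
  src <- snapFacilities(fac, cmb)
  expect_equal(nrow(src), 1L)
  expect_setequal(src$ids[[1]], c("a", "b"))
})

test_that("a facility stranded on barriers raises an error naming it", {
  g <- makeGrid(9)
  cmb <- uniformClass(g, "wetland")
  fac <- data.frame(id = "lost", x = 135, y = 135)
  expect_error(snapFacilities(fac, cmb, radius = 3L), "lost")
})

test_that("directional slope is rise over run and antisymmetric", {
  g <- makeGrid(3)
  dem <- Dem(g, matrix(c(100, 100, 100, 103, 103, 103, 100, 100, 100), 3, 3))
  expect_equal(directionalSlope(flatDem(g), c(1, 1), c(1, 2)), 0)
  expect_equal(directionalSlope(dem, c(1, 1), c(1, 2)), 0.1)
  expect_equal(directionalSlope(dem, c(2, 1), c(1, 2)), 3 / (30 * sqrt(2)))
  expect_error(directionalSlope(dem, c(1, 1), c(1, 3)), "adjacent")
  # antisymmetry on random DEMs
  for (seed in 1:3) {
    set.seed(seed)
    d <- Dem(g, matrix(stats::runif(9, 800, 2400), 3, 3))
    off <- rbind(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
    for (i in seq_len(nrow(off))) {
      a <- c(2, 2); b <- a + off[i, ]
      expect_equal(directionalSlope(d, a, b), -directionalSlope(d, b, a))
    }
  }
})
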