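test_that("default parameters encode the study-region structure", {
  p <- kigomaLikeDefaults()
  expect_equal(unname(p$classFractions[c("grassland", "cropland",
                                         "forestland", "water")]),
               c(0.34, 0.08, 0.34, 0.14))
  expect_equal(p$nCouncils, 8L)
  expect_equal(p$nFacilitiesEmonc, 11L)
  expect_equal(p$nFacilitiesTotal, 127L)
  expect_equal(p$elevationRange, c(800, 2400))
  expect_equal(p$boatOffset, 60)
  expect_error(kigomaLikeDefaults(bogus = 1), "unknown")
  expect_error(kigomaLikeDefaults(classFractions = c(grassland = 1.2)),
               "sum")
})

test_that("realized class fractions hit their targets within 2 points", {
  for (seed in c(1, 42)) {
    p <- smallParams(seed)
    lc <- generateLandcover(p)
    v <- gridValues(lc$landcover)
    frac <- table(factor(v, levels = landClasses()$code)) / length(v)
    got <- stats::setNames(as.numeric(frac), landClasses()$name)
    expect_gte(got[["grassland"]], 0.32); expect_lte(got[["grassland"]], 0.36)
    expect_equal(got[["forestland"]], 0.34, tolerance = 0.06)
    expect_equal(got[["water"]], 0.14, tolerance = 0.15)
    expect_equal(got[["cropland"]], 0.08, tolerance = 0.25)
    expect_false(anyNA(v))
  }
})

test_that("the DEM stays inside the configured elevation range", {
  lc <- generateLandcover(smallParams(3))
  e <- gridValues(lc$dem)
  expect_gte(min(e), 800)
  expect_lte(max(e), 2400)
})

test_that("generation is deterministic per seed", {
  p <- smallParams(5)
  a <- simulateRegion(p)
  b <- simulateRegion(p)
  expect_identical(gridValues(a@combined), gridValues(b@combined))
  expect_identical(gridValues(a@dem), gridValues(b@dem))
  expect_identical(gridValues(a@births), gridValues(b@births))
  expect_identical(a@facilities, b@facilities)
  c2 <- simulateRegion(smallParams(6))
  expect_false(identical(gridValues(a@combined), gridValues(c2@combined)))
})

test_that("every town is connected to the road network", {
  p <- smallParams(2)
  lc <- generateLandcover(p)
  net <- generateNetwork(p, lc$landcover, lc$dem)
  towns <- net$towns
  key <- function(x, y) paste(round(x, 3), round(y, 3))
  ids <- stats::setNames(seq_len(nrow(towns)), key(towns$x, towns$y))
  edges <- do.call(rbind, lapply(net$roads@features, function(f) {
    a <- ids[key(f$coords[1, 1], f$coords[1, 2])]
    b <- ids[key(f$coords[nrow(f$coords), 1], f$coords[nrow(f$coords), 2])]
    c(a, b)
  }))
  edges <- edges[stats::complete.cases(edges), , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(towns), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  expect_true(igraph::is_connected(g))
})

test_that("rivers descend monotonically and boat routes stay on water", {
  p <- smallParams(2)
  lc <- generateLandcover(p)
  net <- generateNetwork(p, lc$landcover, lc$dem)
  for (f in net$rivers@features) {
    rc <- xyToCell(lc$landcover@grid, f$coords[, 1], f$coords[, 2])
    elev <- gridValues(lc$dem)[cbind(rc$row, rc$col)]
    expect_true(all(diff(elev) <= 0))
  }
  expect_gte(length(net$boatRoutes@features), 1L)
  cmb <- buildCombinedLandcover(lc$landcover, net$rivers, net$roads,
                                net$boatRoutes)
  boat <- which(gridValues(cmb) == landClassCode("boat_route"))
  # the route runs offshore: nearly all boat cells sit on open water (dock
  # spurs deliberately touch the shoreline)
  expect_gte(mean(gridValues(lc$landcover)[boat] == landClassCode("water")),
             0.9)
  # the offshore main-route vertices themselves are on water
  main <- net$boatRoutes@features[[1]]
  rcM <- xyToCell(lc$landcover@grid, main$coords[, 1], main$coords[, 2])
  expect_true(all(gridValues(lc$landcover)[cbind(rcM$row, rcM$col)] ==
                    landClassCode("water")))
})

test_that("births conserve the total and concentrate on settlements", {
  p <- smallParams(4)
  region <- simulateRegion(p)
  expect_equal(sum(gridValues(region@births)), p$birthsTotal)
  # mean birth density on settlement-covered birth cells vs other land
  bg <- region@births@grid
  idx <- expand.grid(row = seq_len(bg@nRows), col = seq_len(bg@nCols))
  ctr <- cellCenter(bg, idx$row, idx$col)
  rc <- xyToCell(region@landcover@grid, ctr[, 1], ctr[, 2])
  ok <- !is.na(rc$row)
  cls <- gridValues(region@landcover)[cbind(rc$row[ok], rc$col[ok])]
  b <- gridValues(region@births)[cbind(idx$row[ok], idx$col[ok])]
  mSet <- mean(b[cls == landClassCode("settlement")])
  mLand <- mean(b[!(cls %in% c(landClassCode("settlement"),
                               landClassCode("water")))])
  expect_equal(mSet / mLand, p$settlementBirthWeight, tolerance = 0.1)

  # unweighted births are uniform over non-water land
  pu <- smallParams(4, settlementBirthWeight = 1)
  ru <- simulateRegion(pu)
  bu <- gridValues(ru@births)[cbind(idx$row[ok], idx$col[ok])]
  land <- cls != landClassCode("water")
  expect_lt(stats::sd(bu[land]) / mean(bu[land]), 0.2)
})

test_that("facilities land on passable cells with the expected care mix", {
  region <- simulateRegion(smallParams(7))
  fac <- region@facilities
  expect_equal(sum(fac$is_emonc), 3L)
  expect_equal(nrow(fac), 24L)
  rc <- xyToCell(region@combined@grid, fac$x, fac$y)
  cls <- gridValues(region@combined)[cbind(rc$row, rc$col)]
  expect_false(any(cls %in% barrierCodes()))
  expect_true(all(fac$care_level %in% careLevels()))
  expect_true("CEmONC" %in% fac$care_level[fac$is_emonc])
})

test_that("councils partition the grid into the requested number of units", {
  region <- simulateRegion(smallParams(8))
  lab <- gridValues(region@councils)
  expect_equal(sort(unique(as.vector(lab))), 1:4)
  expect_equal(length(unitNames(region@councils)), 4L)
  expect_false(anyNA(lab))
})

test_that("undersized settlement fractions are reported helpfully", {
  p <- smallParams(1, classFractions = c(grassland = 0.5, cropland = 0.2,
                                         forestland = 0.25,
                                         settlement = 0.0005),
                   nTowns = 50L)
  lc <- generateLandcover(p)
  expect_error(generateNetwork(p, lc$landcover, lc$dem), "settlement")
})
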