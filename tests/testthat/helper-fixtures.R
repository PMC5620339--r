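# Shared fixtures: everything is generated in code at test time.

makeGrid <- function(n, m = n, cs = 30) GridSpec(n, m, cellSize = cs)

uniformClass <- function(grid, name) ClassRaster(grid, landClassCode(name))

flatDem <- function(grid, elev = 1000) Dem(grid, elev)

# Random mixed-class landscape with barriers and a rough DEM, for
# engine-vs-oracle comparisons. Guaranteed to keep the source passable.
randomLandscape <- function(seed, n = 40, cs = 30) {
  set.seed(seed)
  grid <- makeGrid(n, cs = cs)
  pool <- c("forestland", "grassland", "cropland", "settlement", "other_land",
            "wetland", "river_barrier", "boat_route", "major_road",
            "secondary_road", "local_road_all", "local_road_walk")
  prob <- c(.16, .16, .12, .08, .08, .08, .05, .05, .08, .06, .05, .03)
  codes <- matrix(landClassCode(sample(pool, n * n, TRUE, prob)), n, n)
  dem <- Dem(grid, matrix(1000 + 400 * stats::runif(n * n), n, n))
  # a passable source cell
  src <- which(!matrix(codes %in% barrierCodes(), n, n), arr.ind = TRUE)
  src <- src[sample.int(nrow(src), 1L), , drop = FALSE]
  list(combined = ClassRaster(grid, codes), dem = dem, source = src,
       grid = grid)
}

# Small synthetic-region parameters used by unit tests (fast to generate).
smallParams <- function(seed = 1, ...) {
  kigomaLikeDefaults(nRows = 150L, nCols = 150L, cellSize = 140,
                     nTowns = 12L, nCouncils = 4L, nFacilitiesEmonc = 3L,
                     nFacilitiesTotal = 24L, riverCount = 2L,
                     birthsTotal = 5000, seed = seed, ...)
}

# The default study-scale region and its pipeline results are expensive;
# build them once per test run and share across test files.
.fixtureCache <- new.env(parent = emptyenv())

defaultRegion <- function() {
  if (is.null(.fixtureCache$region))
    .fixtureCache$region <- simulateRegion(kigomaLikeDefaults())
  .fixtureCache$region
}

defaultPipeline <- function() {
  if (is.null(.fixtureCache$pipeline))
    .fixtureCache$pipeline <- suppressMessages(runPipeline(defaultRegion()))
  .fixtureCache$pipeline
}
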