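# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Repeated box blur (moving mean) along both axes: cheap correlated field.
boxBlur <- function(M, radius, times = 3L) {
  blurCols <- function(M, r) {
    n <- nrow(M)
    cs <- rbind(0, apply(M, 2, cumsum))
    lo <- pmax(0L, seq_len(n) - r - 1L)
    hi <- pmin(n, seq_len(n) + r)
    (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
  }
  for (i in seq_len(times)) {
    M <- blurCols(M, radius)
    M <- t(blurCols(t(M), radius))
  }
  M
}

# Correlated uniform-ish random field scaled to [0, 1].
smoothField <- function(n, m, radius) {
  f <- boxBlur(matrix(stats::runif(n * m), n, m), radius)
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(0.5, n, m))
  (f - rng[1]) / diff(rng)
}

#' Default synthetic-landscape parameters
#'
#' A desk-scale landscape whose statistical structure mirrors the study
#' region: land cover fractions of grassland 34%, cropland 8%, forest 34%
#' and water 14% (the remainder split among settlement, other land and
#' wetland), elevations spanning 800-2,400 m with highlands toward the
#' north and south edges and a lake along the west, 8 administrative
#' councils, and 11 EmONC facilities among 127 candidate sites. The boat
#' route runs 60 m offshore. Every quantity is overridable.
#'
#' @param ... named overrides of any default parameter.
#' @return A named list of landscape parameters (see the vignette for the
#'   meaning and units of each).
#' @examples
#' p <- kigomaLikeDefaults(seed = 7, nRows = 120, nCols = 120)
#' p$classFractions
#' @export
kigomaLikeDefaults <- function(...) {
  p <- list(
    # 1500 x 1500 cells of 140 m: a 210 x 210 km region (~44,100 km^2),
    # matching the study region's area and hence its ratio of facility
    # spacing to per-mode 2-hour travel ranges, at a desk-scale cell count.
    nRows = 1500L, nCols = 1500L, cellSize = 140,
    originX = 0, originY = 0, crs = "WGS84/UTM 35S",
    classFractions = c(grassland = 0.34, cropland = 0.08, forestland = 0.34,
                       water = 0.14, settlement = 0.04, other_land = 0.03,
                       wetland = 0.03),
    elevationRange = c(800, 2400),
    nTowns = 120L, nCouncils = 8L,
    nFacilitiesEmonc = 11L, nFacilitiesTotal = 127L,
    roadDensity = 0.05,         # km of road per km^2
    riverCount = 5L,
    lakeOnWest = TRUE,
    boatOffset = 60,            # metres offshore
    birthsTotal = 83000,
    birthCellSize = 100,
    settlementBirthWeight = 50,
    correlationRadius = 8L,     # cells; patch contiguity of the cover field
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (any(p$classFractions < 0) || sum(p$classFractions) > 1 + 1e-9)
    stop("class fractions must be non-negative and sum to at most 1")
  if (p$nFacilitiesEmonc < 1L) stop("need at least one EmONC facility")
  if (p$boatOffset <= 0) stop("boatOffset must be positive")
  p
}

paramsGrid <- function(params) {
  GridSpec(params$nRows, params$nCols, params$cellSize,
           params$originX, params$originY, params$crs)
}

#' Generate synthetic land cover and DEM
#'
#' Land cover is a correlated random field thresholded by rank so realized
#' class fractions match the targets to within a cell. Open water forms a
#' western lake strip (when \code{lakeOnWest}) with a noisy shoreline;
#' wetlands occupy the lowest-elevation land (drainage); the remaining
#' classes are assigned by field quantiles so patches are contiguous. The
#' DEM is an independent smooth field combined with a north/south highland
#' profile, scaled exactly to \code{elevationRange}. Deterministic per
#' seed.
#'
#' @param params from \code{\link{kigomaLikeDefaults}}.
#' @return list with \code{landcover} (\linkS4class{ClassRaster}) and
#'   \code{dem} (\linkS4class{Dem}).
#' @export
generateLandcover <- function(params = kigomaLikeDefaults()) {
  grid <- paramsGrid(params)
  n <- grid@nRows; m <- grid@nCols
  fr <- params$classFractions
  withSeed(params$seed, {
    fieldCover <- smoothField(n, m, params$correlationRadius)
    fieldDem <- smoothField(n, m, params$correlationRadius * 2L)
    fieldShore <- smoothField(n, m, params$correlationRadius)

    # DEM: highlands at the north and south edges plus smooth relief
    rowFrac <- matrix((seq_len(n) - 0.5) / n, n, m)
    profile <- (2 * rowFrac - 1)^2
    z <- 0.6 * profile + 0.4 * fieldDem
    z <- (z - min(z)) / (max(z) - min(z))
    elev <- params$elevationRange[1] + diff(params$elevationRange) * z

    codes <- matrix(NA_integer_, n, m)
    total <- n * m

    # lake: western strip with a wiggly shoreline
    wWater <- fr["water"]
    if (!is.na(wWater) && wWater > 0) {
      colFrac <- matrix(rep((seq_len(m) - 0.5) / m, each = n), n, m)
      score <- colFrac + 0.15 * (fieldShore - 0.5)
      if (!params$lakeOnWest) score <- -score
      nw <- round(wWater * total)
      ordW <- order(score)
      codes[ordW[seq_len(nw)]] <- landClassCode("water")
      # lakeside cells are the lowest terrain; tilt the DEM toward the shore
      elev[!is.na(codes)] <- params$elevationRange[1]
    }

    land <- which(is.na(codes))
    # wetlands along low-elevation drainage
    wWet <- fr["wetland"]
    if (!is.na(wWet) && wWet > 0) {
      nwet <- round(wWet * total)
      ord <- land[order(elev[land], fieldCover[land])]
      codes[ord[seq_len(min(nwet, length(ord)))]] <- landClassCode("wetland")
      land <- which(is.na(codes))
    }

    # remaining classes by rank of the cover field: contiguous patches
    rest <- c("forestland", "grassland", "cropland", "other_land",
              "settlement")
    restFr <- fr[rest]
    restFr[is.na(restFr)] <- 0
    ord <- land[order(fieldCover[land])]
    counts <- round(restFr / sum(restFr) * length(ord))
    counts[length(counts)] <- length(ord) - sum(counts[-length(counts)])
    at <- 1L
    for (i in seq_along(rest)) {
      if (counts[i] <= 0) next
      codes[ord[at:(at + counts[i] - 1L)]] <- landClassCode(rest[i])
      at <- at + counts[i]
    }
    list(landcover = ClassRaster(grid, codes), dem = Dem(grid, elev))
  })
}

# greedy farthest-point sampling of k cells from candidate (row, col) set
farthestPoints <- function(cand, k, start = NULL) {
  if (nrow(cand) == 0L || k < 1L) return(cand[0, , drop = FALSE])
  picked <- integer(0)
  first <- if (is.null(start)) sample.int(nrow(cand), 1L) else start
  picked <- first
  d2min <- (cand$row - cand$row[first])^2 + (cand$col - cand$col[first])^2
  while (length(picked) < min(k, nrow(cand))) {
    nxt <- which.max(d2min)
    picked <- c(picked, nxt)
    d2 <- (cand$row - cand$row[nxt])^2 + (cand$col - cand$col[nxt])^2
    d2min <- pmin(d2min, d2)
  }
  cand[picked, , drop = FALSE]
}

# fraction of sampled points along segment a-b falling on water cells
segmentWaterFrac <- function(landcover, a, b) {
  grid <- landcover@grid
  L <- sqrt(sum((b - a)^2))
  k <- max(2L, ceiling(L / grid@cellSize))
  t <- seq(0, 1, length.out = k)
  rc <- xyToCell(grid, a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  ok <- !is.na(rc$row)
  if (!any(ok)) return(0)
  mean(landcover@values[cbind(rc$row[ok], rc$col[ok])] ==
         landClassCode("water"), na.rm = TRUE)
}

#' Generate the synthetic transport network
#'
#' Towns are sampled in settlement patches (greedy farthest-point, so they
#' spread over the region). Roads are the minimum spanning tree over towns
#' plus extra short edges up to the target road density, with edge weights
#' penalized for crossing water so roads hug the land; edges are classed
#' major / secondary / local by betweenness rank and local edges split into
#' car-, motorcycle/bicycle- and walking-only roads. Rivers descend from
#' highland sources along steepest-descent paths (elevation non-increasing
#' by construction) until they reach the lake or the grid edge. The boat
#' route parallels the western shoreline \code{boatOffset} metres into the
#' lake, and shoreline towns are connected to it by dock spurs.
#'
#' @param params from \code{\link{kigomaLikeDefaults}}.
#' @param landcover,dem from \code{\link{generateLandcover}}.
#' @return list with VectorLayers \code{roads}, \code{rivers},
#'   \code{boatRoutes}, a data.frame \code{towns} (row, col, x, y) and a
#'   data.frame \code{docks} (x, y).
#' @export
generateNetwork <- function(params, landcover, dem) {
  grid <- landcover@grid
  cs <- grid@cellSize
  withSeed(params$seed + 1L, {
    setCells <- which(landcover@values == landClassCode("settlement"),
                      arr.ind = TRUE)
    if (nrow(setCells) < params$nTowns)
      stop("not enough settlement cells to place ", params$nTowns,
           " towns; increase the settlement class fraction")
    cand <- data.frame(row = setCells[, 1], col = setCells[, 2])
    towns <- farthestPoints(cand, params$nTowns)
    ctr <- cellCenter(grid, towns$row, towns$col)
    towns$x <- ctr[, 1]; towns$y <- ctr[, 2]

    # town graph: complete, weights = length * (1 + 5 * water fraction)
    nT <- nrow(towns)
    pairs <- which(upper.tri(matrix(TRUE, nT, nT)), arr.ind = TRUE)
    len <- sqrt((towns$x[pairs[, 1]] - towns$x[pairs[, 2]])^2 +
                  (towns$y[pairs[, 1]] - towns$y[pairs[, 2]])^2)
    wfrac <- vapply(seq_len(nrow(pairs)), function(i) {
      segmentWaterFrac(landcover,
                       c(towns$x[pairs[i, 1]], towns$y[pairs[i, 1]]),
                       c(towns$x[pairs[i, 2]], towns$y[pairs[i, 2]]))
    }, numeric(1))
    w <- len * (1 + 5 * wfrac)
    g <- igraph::make_empty_graph(n = nT, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs))
    igraph::E(g)$weight <- w
    igraph::E(g)$length <- len
    igraph::E(g)$idx <- seq_len(igraph::ecount(g))
    mst <- igraph::mst(g)
    inTree <- logical(igraph::ecount(g))
    inTree[igraph::E(mst)$idx] <- TRUE

    # extra edges, shortest first, until the target road density
    areaKm2 <- (grid@nRows * cs / 1000) * (grid@nCols * cs / 1000)
    targetKm <- params$roadDensity * areaKm2
    keep <- inTree
    totKm <- sum(len[keep]) / 1000
    ord <- order(w)
    for (i in ord) {
      if (totKm >= targetKm) break
      if (keep[i]) next
      keep[i] <- TRUE
      totKm <- totKm + len[i] / 1000
    }

    roadG <- igraph::make_empty_graph(n = nT, directed = FALSE)
    roadG <- igraph::add_edges(roadG, t(pairs[keep, , drop = FALSE]))
    igraph::E(roadG)$weight <- w[keep]
    eb <- igraph::edge_betweenness(roadG, weights = igraph::E(roadG)$weight)
    rk <- rank(-eb, ties.method = "first")
    nE <- sum(keep)
    classes <- character(nE)
    classes[rk <= ceiling(0.2 * nE)] <- "major_road"
    classes[rk > ceiling(0.2 * nE) & rk <= ceiling(0.5 * nE)] <- "secondary_road"
    localIdx <- which(classes == "")
    localKind <- sample(c("local_road_all", "local_road_moto_bike",
                          "local_road_walk"), length(localIdx),
                        replace = TRUE, prob = c(0.5, 0.3, 0.2))
    classes[localIdx] <- localKind

    keptPairs <- pairs[keep, , drop = FALSE]
    roadFeats <- lapply(seq_len(nE), function(i) {
      list(coords = cbind(c(towns$x[keptPairs[i, 1]], towns$x[keptPairs[i, 2]]),
                          c(towns$y[keptPairs[i, 1]], towns$y[keptPairs[i, 2]])),
           class = classes[i])
    })

    # rivers: steepest descent from spaced highland sources
    riverFeats <- list()
    if (params$riverCount > 0) {
      hi <- which(dem@values >= stats::quantile(dem@values, 0.9),
                  arr.ind = TRUE)
      hiC <- data.frame(row = hi[, 1], col = hi[, 2])
      srcs <- farthestPoints(hiC, params$riverCount)
      water <- landClassCode("water")
      for (s in seq_len(nrow(srcs))) {
        r <- srcs$row[s]; cc <- srcs$col[s]
        path <- cellCenter(grid, r, cc)
        for (step in seq_len(grid@nRows + grid@nCols)) {
          nb <- neighborOffsets(8L)
          rr <- r + nb[, "dr"]; ncl <- cc + nb[, "dc"]
          ok <- rr >= 1 & rr <= grid@nRows & ncl >= 1 & ncl <= grid@nCols
          if (!any(ok)) break
          e <- dem@values[cbind(rr[ok], ncl[ok])]
          j <- which(ok)[which.min(e)]
          if (dem@values[rr[j], ncl[j]] >= dem@values[r, cc]) break
          r <- rr[j]; cc <- ncl[j]
          path <- rbind(path, cellCenter(grid, r, cc))
          if (landcover@values[r, cc] == water) break
        }
        if (nrow(path) >= 5)
          riverFeats[[length(riverFeats) + 1L]] <-
            list(coords = path, class = "river_barrier")
      }
    }

    # boat route offset into the lake, plus dock spurs near shoreline towns
    boatFeats <- list()
    docks <- data.frame(x = numeric(0), y = numeric(0))
    if (params$lakeOnWest &&
        any(landcover@values == landClassCode("water"))) {
      water <- landcover@values == landClassCode("water")
      shoreCol <- apply(water, 1, function(rw) {
        run <- which(!rw)[1]
        if (is.na(run)) length(rw) else run - 1L
      })
      yRows <- cellCenter(grid, seq_len(grid@nRows), 1L)[, 2]
      shoreX <- grid@originX + shoreCol * cs
      boatX <- shoreX - params$boatOffset
      okRow <- shoreCol * cs > params$boatOffset + cs / 2
      if (sum(okRow) >= 2) {
        coords <- cbind(boatX[okRow], yRows[okRow])
        boatFeats[[1]] <- list(coords = coords, class = "boat_route")
        # docks: towns within reach of the shore
        for (t in seq_len(nT)) {
          rw <- towns$row[t]
          if (!okRow[rw]) next
          if (towns$x[t] - shoreX[rw] < 20 * cs && towns$x[t] >= shoreX[rw]) {
            dock <- c(shoreX[rw], yRows[rw])
            docks <- rbind(docks, data.frame(x = dock[1], y = dock[2]))
            boatFeats[[length(boatFeats) + 1L]] <- list(
              coords = rbind(c(boatX[rw], yRows[rw]), dock),
              class = "boat_route")
            roadFeats[[length(roadFeats) + 1L]] <- list(
              coords = rbind(dock, c(towns$x[t], towns$y[t])),
              class = "local_road_all")
          }
        }
      }
    }

    list(roads = VectorLayer("polyline", roadFeats, grid@crs),
         rivers = VectorLayer("polyline", riverFeats, grid@crs),
         boatRoutes = VectorLayer("polyline", boatFeats, grid@crs),
         towns = towns, docks = docks)
  })
}

#' Generate synthetic facilities, births and councils
#'
#' EmONC facilities are placed in the densest towns with a care-level mix
#' echoing the study region (mostly fully functional CEmONC, one partially
#' functional CEmONC, a couple of partially functional BEmONC); the
#' remaining candidate sites are non-EmONC facilities in smaller towns and
#' settlement cells. Births are distributed over non-water cells with a
#' multiplicative settlement weight, aggregated onto the coarser birth
#' lattice, and sum exactly to \code{birthsTotal}. Councils are a raster
#' Voronoi partition around spread town seeds.
#'
#' @param params from \code{\link{kigomaLikeDefaults}}.
#' @param landcover from \code{\link{generateLandcover}}.
#' @param towns town table from \code{\link{generateNetwork}}.
#' @return list with \code{facilities} (data.frame), \code{births}
#'   (\linkS4class{BirthRaster}) and \code{councils}
#'   (\linkS4class{AdminUnits}).
#' @export
generatePopulation <- function(params, landcover, towns) {
  grid <- landcover@grid
  withSeed(params$seed + 2L, {
    if (params$birthsTotal <= 0) stop("birthsTotal must be positive")
    # rank towns by surrounding settlement density
    setm <- landcover@values == landClassCode("settlement")
    dens <- vapply(seq_len(nrow(towns)), function(i) {
      rw <- max(1, towns$row[i] - 10):min(grid@nRows, towns$row[i] + 10)
      cl <- max(1, towns$col[i] - 10):min(grid@nCols, towns$col[i] + 10)
      sum(setm[rw, cl])
    }, numeric(1))
    ord <- order(-dens, towns$row, towns$col)

    nE <- params$nFacilitiesEmonc
    nCem <- max(1L, round(nE * 8 / 11))
    nCm1 <- if (nE >= 4L) max(1L, round(nE * 1 / 11)) else 0L
    nBm1 <- max(0L, nE - nCem - nCm1)
    levels <- c(rep("CEmONC", nCem), rep("CEmONC_minus_1", nCm1),
                rep("BEmONC_minus_1", nBm1))

    nTot <- max(params$nFacilitiesTotal, nE)
    emTowns <- ord[rep_len(seq_len(min(nE, length(ord))), nE)]
    restTowns <- if (length(ord) > nE) ord[-seq_len(nE)] else integer(0)
    setCells <- which(setm, arr.ind = TRUE)
    extraN <- nTot - nE - length(restTowns)
    extraIdx <- if (extraN > 0)
      sample.int(nrow(setCells), min(extraN, nrow(setCells))) else integer(0)

    rows <- c(towns$row[emTowns], towns$row[restTowns], setCells[extraIdx, 1])
    cols <- c(towns$col[emTowns], towns$col[restTowns], setCells[extraIdx, 2])
    care <- c(levels, rep("non_EmONC", length(rows) - nE))
    ctr <- cellCenter(grid, rows, cols)
    facilities <- data.frame(
      id = sprintf("fac_%03d", seq_along(rows)),
      x = ctr[, 1], y = ctr[, 2],
      care_level = care,
      is_emonc = care != "non_EmONC",
      stringsAsFactors = FALSE)

    # births: weight 0 on water, settlementBirthWeight on settlement, 1 else
    bcs <- params$birthCellSize
    bGrid <- GridSpec(ceiling(grid@nRows * grid@cellSize / bcs),
                      ceiling(grid@nCols * grid@cellSize / bcs),
                      bcs, grid@originX,
                      # align the north edge of both lattices
                      grid@originY + grid@nRows * grid@cellSize -
                        ceiling(grid@nRows * grid@cellSize / bcs) * bcs,
                      grid@crs)
    idx <- expand.grid(row = seq_len(bGrid@nRows), col = seq_len(bGrid@nCols))
    ctrB <- cellCenter(bGrid, idx$row, idx$col)
    rc <- xyToCell(grid, ctrB[, 1], ctrB[, 2])
    wt <- numeric(nrow(idx))
    inb <- !is.na(rc$row)
    cls <- landcover@values[cbind(rc$row[inb], rc$col[inb])]
    wti <- rep(1, sum(inb))
    wti[cls == landClassCode("water")] <- 0
    wti[cls == landClassCode("settlement")] <- params$settlementBirthWeight
    wt[inb] <- wti
    births <- wt / sum(wt) * params$birthsTotal
    # pin the float total exactly to birthsTotal on the heaviest cell
    imax <- which.max(births)
    births[imax] <- births[imax] + (params$birthsTotal - sum(births))
    bVals <- matrix(0, bGrid@nRows, bGrid@nCols)
    bVals[cbind(idx$row, idx$col)] <- births

    # councils: raster Voronoi around spread town seeds
    seeds <- farthestPoints(towns[, c("row", "col")], params$nCouncils,
                            start = ord[1])
    rr <- matrix(seq_len(grid@nRows), grid@nRows, grid@nCols)
    cc <- matrix(rep(seq_len(grid@nCols), each = grid@nRows),
                 grid@nRows, grid@nCols)
    best <- matrix(Inf, grid@nRows, grid@nCols)
    lab <- matrix(1L, grid@nRows, grid@nCols)
    for (i in seq_len(nrow(seeds))) {
      d2 <- (rr - seeds$row[i])^2 + (cc - seeds$col[i])^2
      upd <- d2 < best
      lab[upd] <- i
      best[upd] <- d2[upd]
    }
    councils <- new("AdminUnits", grid = grid, values = lab,
                    unitNames = sprintf("council_%02d", seq_len(nrow(seeds))),
                    polygons = NULL)

    list(facilities = facilities, births = BirthRaster(bGrid, bVals),
         councils = councils)
  })
}

#' Simulate a complete synthetic study region
#'
#' Runs the three generator stages in order (land cover and DEM, transport
#' network, population) and assembles the combined land-cover raster by
#' burning rivers, roads and boat routes over the base cover; major-road
#' cells whose underlying cover is settlement are recoded as major roads
#' crossing residential areas. Fully deterministic per seed.
#'
#' @param params from \code{\link{kigomaLikeDefaults}}.
#' @return A \linkS4class{SyntheticRegion}.
#' @examples
#' \donttest{
#' region <- simulateRegion(kigomaLikeDefaults(nRows = 80, nCols = 80,
#'                                             nTowns = 8, nCouncils = 4,
#'                                             nFacilitiesTotal = 20,
#'                                             nFacilitiesEmonc = 3, seed = 2))
#' region
#' }
#' @export
simulateRegion <- function(params = kigomaLikeDefaults()) {
  lc <- generateLandcover(params)
  net <- generateNetwork(params, lc$landcover, lc$dem)
  pop <- generatePopulation(params, lc$landcover, net$towns)
  combined <- buildCombinedLandcover(lc$landcover, net$rivers, net$roads,
                                     net$boatRoutes)
  v <- combined@values
  resid <- v == landClassCode("major_road") &
    lc$landcover@values == landClassCode("settlement")
  v[resid] <- landClassCode("major_road_residential")
  combined <- ClassRaster(combined@grid, v, combined@nodataCode)
  new("SyntheticRegion", landcover = lc$landcover, dem = lc$dem,
      roads = net$roads, rivers = net$rivers, boatRoutes = net$boatRoutes,
      facilities = pop$facilities, births = pop$births,
      councils = pop$councils, combined = combined, params = params)
}
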