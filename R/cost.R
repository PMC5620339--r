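#' @useDynLib accesscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Per-cell flat speed (km/h, NA = impassable) and anisotropy flag under a
# speed table. Shared by the engine and the oracle.
speedMatrices <- function(combined, table, anisotropicBicycle = FALSE) {
  e <- table@entries
  codes <- landClassCode(e$class)
  speedByCode <- rep(NA_real_, max(landClasses()$code))
  anisoByCode <- rep(FALSE, max(landClasses()$code))
  speedByCode[codes] <- e$speed_kmh
  anisoModes <- "walking"
  if (anisotropicBicycle) anisoModes <- c(anisoModes, "bicycle")
  anisoByCode[codes] <- !is.na(e$mode) & e$mode %in% anisoModes
  v <- combined@values
  speed <- matrix(speedByCode[v], nrow(v), ncol(v))
  aniso <- matrix(anisoByCode[v], nrow(v), ncol(v))
  aniso[is.na(aniso)] <- FALSE
  list(speed = speed, aniso = aniso)
}

# both witness cells barriers => the step squeezes between barrier corners
cornerForbidden <- function(passable, ur, uc, dr, dc) {
  n <- nrow(passable); m <- ncol(passable)
  sr <- sign(dr); sc <- sign(dc)
  if (abs(dr) == 1 && abs(dc) == 1) {
    w1r <- ur + dr; w1c <- uc
    w2r <- ur;      w2c <- uc + dc
  } else if (abs(dc) == 2) {
    w1r <- ur;      w1c <- uc + sc
    w2r <- ur + dr; w2c <- uc + sc
  } else {
    w1r <- ur + sr; w1c <- uc
    w2r <- ur + sr; w2c <- uc + dc
  }
  wOK <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    res <- rep(FALSE, length(r))
    res[ok] <- passable[cbind(r[ok], c[ok])]
    res
  }
  !wOK(w1r, w1c) & !wOK(w2r, w2c)
}

#' Travel time of one step between adjacent cells
#'
#' The cost of moving from the centre of \code{from} to the centre of
#' \code{to}: each cell contributes half the step length at its own
#' effective speed (harmonic half-cell composition),
#' \code{d/2 * (1/v_from + 1/v_to)}, in minutes. Both speeds are evaluated
#' with the slope in the direction of travel (\code{from -> to}), so
#' walking steps are direction-asymmetric on slopes while motorized and
#' bicycle steps are symmetric.
#'
#' @param combined combined \linkS4class{ClassRaster}.
#' @param dem \linkS4class{Dem} on the same grid.
#' @param table \linkS4class{SpeedTable}.
#' @param from,to \code{c(row, col)} of adjacent cells under
#'   \code{config} connectivity.
#' @param config \linkS4class{EngineConfig}.
#' @param params \linkS4class{ToblerParams}.
#' @param anisotropicBicycle slope-correct bicycle speed too (default FALSE).
#' @return Minutes for the step, or \code{NA} if either cell is impassable.
#' @examples
#' g <- GridSpec(1, 2, cellSize = 30)
#' cr <- ClassRaster(g, landClassCode("boat_route"))
#' edgeTime(cr, Dem(g, 0), defaultSpeedTable("walking"), c(1, 1), c(1, 2))
#' @export
edgeTime <- function(combined, dem, table, from, to,
                     config = EngineConfig(), params = ToblerParams(),
                     anisotropicBicycle = FALSE) {
  stopIfGridMismatch(combined, dem, "land cover and DEM")
  dr <- to[1] - from[1]; dc <- to[2] - from[2]
  off <- neighborOffsets(config@connectivity)
  if (!any(off[, "dr"] == dr & off[, "dc"] == dc))
    stop("cells are not adjacent under ", config@connectivity, "-connectivity")
  sm <- speedMatrices(combined, table, anisotropicBicycle)
  vFromFlat <- sm$speed[from[1], from[2]]
  vToFlat <- sm$speed[to[1], to[2]]
  if (is.na(vFromFlat) || is.na(vToFlat)) return(NA_real_)
  d <- sqrt(dr^2 + dc^2) * combined@grid@cellSize
  s <- (dem@values[to[1], to[2]] - dem@values[from[1], from[2]]) / d
  tob <- toblerMultiplier(s, params)
  vFrom <- vFromFlat * if (sm$aniso[from[1], from[2]]) tob else 1
  vTo <- vToFlat * if (sm$aniso[to[1], to[2]]) tob else 1
  60 * (d / 1000) * 0.5 * (1 / vFrom + 1 / vTo)
}

# normalize/validate a source specification into a (row, col) matrix of
# passable cells
resolveSources <- function(sources, speed) {
  if (is.data.frame(sources)) sources <- cbind(sources$row, sources$col)
  sources <- matrix(as.integer(sources), ncol = 2)
  if (nrow(sources) == 0L) stop("at least one source cell is required")
  pass <- !is.na(speed[sources])
  if (!any(pass)) stop("all source cells lie on barrier cells")
  if (!all(pass)) {
    warning(sum(!pass), " source cell(s) on barriers dropped")
    sources <- sources[pass, , drop = FALSE]
  }
  sources
}

#' Accumulate minimum travel time to the nearest facility
#'
#' Multi-source least-cost accumulation over the combined land-cover
#' friction surface: for every cell, the minimum over all sources and all
#' paths of the summed step times (\code{\link{edgeTime}}), computed by an
#' exact Dijkstra sweep implemented in C++. Slopes are always evaluated in
#' the traveller's direction of motion — toward the facility — even though
#' the computation propagates outward from the sources.
#'
#' @param combined combined \linkS4class{ClassRaster}.
#' @param dem \linkS4class{Dem} on the same grid.
#' @param table \linkS4class{SpeedTable} for the scenario.
#' @param sources source cells: a data.frame/matrix of (row, col), e.g.
#'   from \code{\link{snapFacilities}}.
#' @param config \linkS4class{EngineConfig}.
#' @param params \linkS4class{ToblerParams}.
#' @param anisotropicBicycle slope-correct bicycle speed too.
#' @return A \linkS4class{TravelTimeSurface} in minutes; \code{NA} =
#'   unreachable.
#' @seealso \code{\link{oracleTravelTime}} for the explicit-graph reference
#'   implementation used in testing.
#' @export
accumulateTravelTime <- function(combined, dem, table, sources,
                                 config = EngineConfig(),
                                 params = ToblerParams(),
                                 anisotropicBicycle = FALSE) {
  stopIfGridMismatch(combined, dem, "land cover and DEM")
  sm <- speedMatrices(combined, table, anisotropicBicycle)
  sources <- resolveSources(sources, sm$speed)
  minutes <- cpp_accumulate(sm$speed, sm$aniso, dem@values,
                            combined@grid@cellSize, config@connectivity,
                            sources, params@steepness, params@offset,
                            params@normalizeToFlat)
  TravelTimeSurface(combined@grid, minutes, table@scenarioId)
}

#' Explicit-graph reference travel-time computation
#'
#' Independent oracle with the same contract as
#' \code{\link{accumulateTravelTime}}: materializes the full weighted
#' directed graph (one node per passable cell, one arc per ordered adjacent
#' pair, weighted by the inward step time) and delegates shortest paths to
#' \code{igraph::distances}. Intended for small grids (about 1e4 cells).
#'
#' @inheritParams accumulateTravelTime
#' @return A \linkS4class{TravelTimeSurface}.
#' @export
oracleTravelTime <- function(combined, dem, table, sources,
                             config = EngineConfig(),
                             params = ToblerParams(),
                             anisotropicBicycle = FALSE) {
  stopIfGridMismatch(combined, dem, "land cover and DEM")
  sm <- speedMatrices(combined, table, anisotropicBicycle)
  sources <- resolveSources(sources, sm$speed)
  n <- nrow(sm$speed); m <- ncol(sm$speed)
  cs <- combined@grid@cellSize
  passable <- !is.na(sm$speed)
  speedVec <- as.vector(sm$speed)
  anisoVec <- as.vector(sm$aniso)
  elevVec <- as.vector(dem@values)

  offs <- neighborOffsets(config@connectivity)
  eFrom <- integer(0); eTo <- integer(0); eW <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, "dr"]; dc <- offs[k, "dc"]
    rf <- seq(max(1L, 1L - dr), min(n, n - dr))
    cf <- seq(max(1L, 1L - dc), min(m, m - dc))
    if (!length(rf) || !length(cf)) next
    from <- rep(rf, times = length(cf)) +
      n * (rep(cf, each = length(rf)) - 1L)
    to <- from + dr + n * dc
    keep <- passable[from] & passable[to]
    if (abs(dr) + abs(dc) >= 2) {
      ur <- rep(rf, times = length(cf)); uc <- rep(cf, each = length(rf))
      keep <- keep & !cornerForbidden(passable, ur, uc, dr, dc)
    }
    from <- from[keep]; to <- to[keep]
    if (!length(from)) next
    d <- sqrt(dr^2 + dc^2) * cs
    s <- (elevVec[to] - elevVec[from]) / d
    tob <- toblerMultiplier(s, params)
    vFrom <- speedVec[from] * ifelse(anisoVec[from], tob, 1)
    vTo <- speedVec[to] * ifelse(anisoVec[to], tob, 1)
    w <- 60 * (d / 1000) * 0.5 * (1 / vFrom + 1 / vTo)
    eFrom <- c(eFrom, from); eTo <- c(eTo, to); eW <- c(eW, w)
  }

  g <- igraph::make_empty_graph(n = n * m, directed = TRUE)
  g <- igraph::add_edges(g, rbind(eFrom, eTo))
  srcIdx <- sources[, 1] + n * (sources[, 2] - 1L)
  # distance from every cell to each source along arc directions
  dmat <- igraph::distances(g, v = srcIdx, mode = "in", weights = eW,
                            algorithm = "dijkstra")
  best <- do.call(pmin, c(split(dmat, seq_len(nrow(dmat))), na.rm = TRUE))
  best[is.infinite(best)] <- NA_real_
  best[!passable] <- NA_real_
  TravelTimeSurface(combined@grid, matrix(best, n, m), table@scenarioId)
}
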