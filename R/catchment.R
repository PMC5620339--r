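#' Classify a travel-time surface into 30-minute zones
#'
#' Reclassifies minutes into incremental bands with closed upper bounds:
#' with the default breaks, 0-30, 31-60, 61-90, 91-120 and over-120. A cell
#' at exactly 120 minutes is good access ("at, or under, 2 hours").
#' Unreachable cells fall in the over-threshold band.
#'
#' @param surface a \linkS4class{TravelTimeSurface}.
#' @param breaks strictly increasing minute bounds; the last break is the
#'   good-access threshold (default \code{c(30, 60, 90, 120)}).
#' @return A \linkS4class{ZoneRaster} (codes 1..5 labelled by
#'   \code{zoneLevels()}).
#' @export
classifyZones <- function(surface, breaks = c(30, 60, 90, 120)) {
  if (length(breaks) == 0L || any(diff(breaks) <= 0) || any(breaks <= 0))
    stop("breaks must be a non-empty strictly increasing positive vector")
  if (length(breaks) != 4L)
    stop("exactly 4 breaks are expected for the 5-band zone scheme")
  m <- surface@values
  z <- matrix(length(breaks) + 1L, nrow(m), ncol(m))  # OVER_120 default
  for (i in rev(seq_along(breaks))) z[!is.na(m) & m <= breaks[i]] <- i
  ZoneRaster(surface@grid, z)
}

#' Two-hour service catchment
#'
#' Boolean mask of cells with travel time at or under the good-access
#' threshold (120 minutes by default). Unreachable cells are outside.
#'
#' @param surface a \linkS4class{TravelTimeSurface}.
#' @param threshold minutes (default 120).
#' @return A \linkS4class{CatchmentMask}.
#' @export
twoHourCatchment <- function(surface, threshold = 120) {
  m <- surface@values
  CatchmentMask(surface@grid, !is.na(m) & m <= threshold)
}

#' All-modes travel-time surface
#'
#' Cell-wise minimum over per-scenario surfaces: the best case where any of
#' the four primary transportation modes may be used. A cell is unreachable
#' only if it is unreachable under every input scenario.
#'
#' @param surfaces list of co-registered \linkS4class{TravelTimeSurface}s.
#' @return A \linkS4class{TravelTimeSurface} with scenarioId "all_modes".
#' @export
allModesMinimum <- function(surfaces) {
  if (length(surfaces) == 0L) stop("need at least one surface")
  g <- surfaces[[1]]@grid
  for (s in surfaces) stopIfGridMismatch(g, s, "travel-time surfaces")
  vals <- lapply(surfaces, function(s) s@values)
  best <- do.call(pmin, c(vals, list(na.rm = TRUE)))
  TravelTimeSurface(g, best, "all_modes")
}

#' Mode-combination map
#'
#' For every cell, the subset of scenarios whose 2-hour catchment contains
#' it, encoded as a bitmask (bit i set = scenario i within threshold). Cells
#' with an empty subset have poor access under every mode. Under the default
#' speed tables the subsets respect the scenario dominance order (a cell
#' reachable on foot is reachable by car; reachable by bicycle implies
#' reachable by motorcycle).
#'
#' @param surfaces named list of co-registered
#'   \linkS4class{TravelTimeSurface}s (names = scenario ids).
#' @param threshold minutes (default 120).
#' @return list with \code{mask}: integer bitmask matrix; \code{scenarios}:
#'   the scenario names, bit order; \code{combo}: factor-coded matrix of
#'   combination labels ("" for none, "+"-joined names otherwise).
#' @export
modeCombinationMap <- function(surfaces, threshold = 120) {
  if (is.null(names(surfaces)) || any(!nzchar(names(surfaces))))
    stop("surfaces must be a named list (scenario ids)")
  g <- surfaces[[1]]@grid
  for (s in surfaces) stopIfGridMismatch(g, s, "travel-time surfaces")
  bits <- matrix(0L, g@nRows, g@nCols)
  for (i in seq_along(surfaces)) {
    v <- surfaces[[i]]@values
    bits <- bits + bitwShiftL(1L, i - 1L) * (!is.na(v) & v <= threshold)
  }
  storage.mode(bits) <- "integer"
  labels <- vapply(seq_len(2^length(surfaces)) - 1L, function(b) {
    paste(names(surfaces)[bitwAnd(b, bitwShiftL(1L, seq_along(surfaces) - 1L)) > 0],
          collapse = "+")
  }, character(1))
  list(mask = bits, scenarios = names(surfaces),
       combo = matrix(labels[bits + 1L], g@nRows, g@nCols))
}

#' Vectorize a zone raster into polygons
#'
#' Decomposes each zone category into axis-aligned rectangles (maximal
#' vertical merges of identical row runs), returned as polygon features
#' tagged with the zone label. Areas are conserved exactly and
#' re-rasterizing onto the same grid reproduces the zone raster cell for
#' cell.
#'
#' @param zones a \linkS4class{ZoneRaster}.
#' @return A \linkS4class{VectorLayer} of polygons with zone-label class
#'   tags.
#' @seealso \code{\link{rasterizeZonePolygons}} for the inverse.
#' @export
vectorizeZones <- function(zones) {
  g <- zones@grid
  v <- zones@values
  cs <- g@cellSize
  feats <- list()
  for (z in seq_along(ZONE_LEVELS)) {
    # row runs of this zone
    runs <- list()  # key (col1,col2) -> row span being grown
    open <- list()
    for (r in seq_len(g@nRows)) {
      rl <- rle(v[r, ] == z)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      keys <- character(0)
      if (any(rl$values)) {
        sel <- which(rl$values)
        keys <- paste(starts[sel], ends[sel])
        for (i in seq_along(sel)) {
          k <- keys[i]
          o <- open[[k]]
          if (!is.null(o) && o$row2 == r - 1L) {
            open[[k]]$row2 <- r
          } else {
            if (!is.null(o)) runs[[length(runs) + 1L]] <- o
            open[[k]] <- list(col1 = starts[sel[i]], col2 = ends[sel[i]],
                              row1 = r, row2 = r)
          }
        }
      }
      # close runs not continued in this row
      stale <- setdiff(names(open), keys)
      for (k in stale) {
        runs[[length(runs) + 1L]] <- open[[k]]
        open[[k]] <- NULL
      }
    }
    for (k in names(open)) runs[[length(runs) + 1L]] <- open[[k]]
    for (o in runs) {
      x1 <- g@originX + (o$col1 - 1L) * cs
      x2 <- g@originX + o$col2 * cs
      y1 <- g@originY + (g@nRows - o$row2) * cs
      y2 <- g@originY + (g@nRows - o$row1 + 1L) * cs
      feats[[length(feats) + 1L]] <- list(
        coords = cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2)),
        class = ZONE_LEVELS[z])
    }
  }
  VectorLayer("polygon", feats, crs = g@crs)
}

#' Rasterize zone polygons back onto a grid
#'
#' Inverse of \code{\link{vectorizeZones}} for axis-aligned zone polygons:
#' every cell whose centre falls inside a polygon gets that polygon's zone
#' code.
#'
#' @param layer polygon \linkS4class{VectorLayer} with zone-label class tags.
#' @param grid target \linkS4class{GridSpec}.
#' @return A \linkS4class{ZoneRaster}.
#' @export
rasterizeZonePolygons <- function(layer, grid) {
  v <- matrix(NA_integer_, grid@nRows, grid@nCols)
  for (f in layer@features) {
    z <- match(f$class, ZONE_LEVELS)
    if (is.na(z)) stop("unknown zone label: ", f$class)
    idx <- windowCells(grid, min(f$coords[, 1]), max(f$coords[, 1]),
                       min(f$coords[, 2]), max(f$coords[, 2]))
    if (is.null(idx)) next
    ctr <- cellCenter(grid, idx$row, idx$col)
    inside <- ctr[, 1] > min(f$coords[, 1]) & ctr[, 1] < max(f$coords[, 1]) &
      ctr[, 2] > min(f$coords[, 2]) & ctr[, 2] < max(f$coords[, 2])
    v[cbind(idx$row[inside], idx$col[inside])] <- z
  }
  if (anyNA(v)) stop("zone polygons do not cover the grid")
  ZoneRaster(grid, v)
}
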