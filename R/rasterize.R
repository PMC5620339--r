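#' Rasterize a vector layer onto a grid
#'
#' Burns vector features into an integer class mask by the cell-centre rule:
#' a cell is burnt when its centre lies within half a cell size of a
#' polyline, strictly inside a polygon, or contains a point. The rule is
#' deterministic and fixed for reproducibility.
#'
#' @param layer a \linkS4class{VectorLayer}.
#' @param grid the target \linkS4class{GridSpec} (same CRS as the layer).
#' @param burnCode integer land-class code to burn, or \code{NULL} to take
#'   each feature's own \code{class} tag (resolved via
#'   \code{\link{landClassCode}}).
#' @return A \linkS4class{ClassRaster} mask: burnt cells carry the code,
#'   all others are nodata (\code{NA}). Features (or parts) outside the grid
#'   are clipped with a warning.
#' @examples
#' g <- GridSpec(5, 5, cellSize = 30)
#' road <- VectorLayer("polyline", list(list(
#'   coords = cbind(c(0, 150), c(75, 75)), class = "major_road")))
#' mask <- rasterizeLayer(road, g)
#' table(gridValues(mask))
#' @export
rasterizeLayer <- function(layer, grid, burnCode = NULL) {
  if (!identical(layer@crs, grid@crs))
    stop("layer CRS (", layer@crs, ") does not match grid CRS (", grid@crs, ")")
  out <- matrix(NA_integer_, grid@nRows, grid@nCols)
  cs <- grid@cellSize
  xmin <- grid@originX; ymin <- grid@originY
  xmax <- xmin + grid@nCols * cs; ymax <- ymin + grid@nRows * cs
  clipped <- FALSE

  for (f in layer@features) {
    code <- if (is.null(burnCode)) landClassCode(f$class) else as.integer(burnCode)
    xy <- f$coords
    if (any(xy[, 1] < xmin | xy[, 1] > xmax | xy[, 2] < ymin | xy[, 2] > ymax))
      clipped <- TRUE
    if (layer@geometryKind == "point") {
      rc <- xyToCell(grid, xy[, 1], xy[, 2])
      ok <- !is.na(rc$row)
      out[cbind(rc$row[ok], rc$col[ok])] <- code
    } else if (layer@geometryKind == "polyline") {
      if (nrow(xy) < 2L) next
      for (i in seq_len(nrow(xy) - 1L)) {
        out <- burnSegment(out, grid, xy[i, ], xy[i + 1L, ], code)
      }
    } else { # polygon: cell centres inside the ring (even-odd rule)
      ring <- xy
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])
      # restrict the point-in-polygon test to the ring's bounding box
      idx <- windowCells(grid, min(ring[, 1]), max(ring[, 1]),
                         min(ring[, 2]), max(ring[, 2]))
      if (is.null(idx)) next
      ctr <- cellCenter(grid, idx$row, idx$col)
      inside <- mgcv::in.out(ring, ctr)
      out[cbind(idx$row[inside], idx$col[inside])] <- code
    }
  }
  if (clipped)
    warning("some features extend outside the grid and were clipped")
  ClassRaster(grid, out)
}

# Candidate cells whose centres may fall in [xlo,xhi] x [ylo,yhi],
# padded by one cell each way to be robust to boundary arithmetic.
windowCells <- function(grid, xlo, xhi, ylo, yhi) {
  cs <- grid@cellSize
  cl <- max(1L, as.integer(floor((xlo - grid@originX) / cs)))       # +1 -1
  cr <- min(grid@nCols, as.integer(floor((xhi - grid@originX) / cs)) + 2L)
  rt <- max(1L, grid@nRows - as.integer(floor((yhi - grid@originY) / cs)) - 1L)
  rb <- min(grid@nRows, grid@nRows - as.integer(floor((ylo - grid@originY) / cs)) + 1L)
  if (cl > cr || rt > rb) return(NULL)
  expand.grid(row = rt:rb, col = cl:cr)
}

# Burn all cells whose centre is within cs/2 of segment p1-p2.
burnSegment <- function(out, grid, p1, p2, code) {
  half <- grid@cellSize / 2
  idx <- windowCells(grid,
                     min(p1[1], p2[1]) - half, max(p1[1], p2[1]) + half,
                     min(p1[2], p2[2]) - half, max(p1[2], p2[2]) + half)
  if (is.null(idx)) return(out)
  ctr <- cellCenter(grid, idx$row, idx$col)
  d <- pointSegmentDistance(ctr[, 1], ctr[, 2], p1, p2)
  hit <- d <= half
  out[cbind(idx$row[hit], idx$col[hit])] <- code
  out
}

# Euclidean distance from points (px, py) to segment p1-p2 (vectorized).
pointSegmentDistance <- function(px, py, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx * vx + vy * vy
  if (len2 == 0) return(sqrt((px - p1[1])^2 + (py - p1[2])^2))
  t <- pmin(1, pmax(0, ((px - p1[1]) * vx + (py - p1[2]) * vy) / len2))
  sqrt((px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2)
}

#' Build the combined land-cover raster
#'
#' Overlays the network layers on the base land cover in a fixed burn
#' order: rivers first (as the internal \code{river_barrier} code), then
#' roads (each feature's own road class), then boat routes. Later burns
#' overwrite earlier ones, so a road cell crossing a river stays passable —
#' implicit bridge semantics; any other order would sever the road network
#' at every crossing.
#'
#' @param base \linkS4class{ClassRaster} of non-road cover classes with no
#'   nodata inside the study region.
#' @param rivers,roads,boatRoutes \linkS4class{VectorLayer} polylines
#'   co-registered with \code{base} (may be empty layers).
#' @return The combined \linkS4class{ClassRaster}.
#' @export
buildCombinedLandcover <- function(base, rivers = NULL, roads = NULL,
                                   boatRoutes = NULL) {
  grid <- base@grid
  vals <- base@values
  overlay <- function(vals, layer, code = NULL) {
    if (is.null(layer) || length(layer@features) == 0L) return(vals)
    if (!identical(layer@crs, grid@crs))
      stop("grid mismatch: overlay layer CRS differs from base grid")
    m <- rasterizeLayer(layer, grid, burnCode = code)@values
    vals[!is.na(m)] <- m[!is.na(m)]
    vals
  }
  vals <- overlay(vals, rivers, landClassCode("river_barrier"))
  vals <- overlay(vals, roads)          # per-feature road class
  vals <- overlay(vals, boatRoutes, landClassCode("boat_route"))
  ClassRaster(grid, vals, base@nodataCode)
}

#' Snap facilities to passable source cells
#'
#' Maps each facility to the grid cell containing its coordinates. A
#' facility landing on a barrier cell (a rasterization artifact: GPS
#' accuracy is metres while cells are tens of metres) is snapped to the
#' nearest passable cell within \code{radius} cells; the snap is reported
#' via \code{message}. Facilities sharing a cell are deduplicated into one
#' source cell that records every id.
#'
#' @param facilities data.frame with columns \code{id}, \code{x}, \code{y}.
#' @param combined the combined \linkS4class{ClassRaster}.
#' @param radius maximum snap distance in cells (default 10).
#' @return data.frame with columns \code{row}, \code{col} and a list-column
#'   \code{ids} of the facility ids mapped to that cell.
#' @export
snapFacilities <- function(facilities, combined, radius = 10L) {
  grid <- combined@grid
  vals <- combined@values
  barrier <- is.na(vals) | matrix(vals %in% barrierCodes(),
                                  nrow(vals), ncol(vals))
  rc <- xyToCell(grid, facilities$x, facilities$y)
  if (anyNA(rc$row))
    stop("facility outside the analysis grid: ",
         paste(facilities$id[is.na(rc$row)], collapse = ", "))
  for (i in seq_len(nrow(facilities))) {
    r <- rc$row[i]; cc <- rc$col[i]
    if (!barrier[r, cc]) next
    # ring search for the nearest passable cell centre
    win_r <- max(1L, r - radius):min(grid@nRows, r + radius)
    win_c <- max(1L, cc - radius):min(grid@nCols, cc + radius)
    cand <- expand.grid(row = win_r, col = win_c)
    cand <- cand[!barrier[cbind(cand$row, cand$col)], , drop = FALSE]
    if (nrow(cand) == 0L)
      stop("facility '", facilities$id[i], "' has no passable cell within ",
           radius, " cells")
    ctr <- cellCenter(grid, cand$row, cand$col)
    d <- sqrt((ctr[, 1] - facilities$x[i])^2 + (ctr[, 2] - facilities$y[i])^2)
    ord <- order(d, cand$row, cand$col)
    rc$row[i] <- cand$row[ord[1]]
    rc$col[i] <- cand$col[ord[1]]
    message("snapped facility '", facilities$id[i], "' off a barrier cell (",
            r, ",", cc, ") -> (", rc$row[i], ",", rc$col[i], ")")
  }
  key <- paste(rc$row, rc$col)
  first <- !duplicated(key)
  out <- data.frame(row = rc$row[first], col = rc$col[first])
  out$ids <- lapply(key[first], function(k) facilities$id[key == k])
  out
}

#' Directional slope between adjacent cells
#'
#' Rise over run in the direction of travel: the elevation difference from
#' \code{from} to \code{to}, divided by the planar distance between the two
#' cell centres. Antisymmetric by construction.
#'
#' @param dem a \linkS4class{Dem}.
#' @param from,to length-2 integer vectors \code{c(row, col)} of adjacent
#'   cells under \code{connectivity}.
#' @param connectivity 8 or 16 (which stencil defines adjacency).
#' @return Dimensionless slope (positive uphill).
#' @examples
#' d <- Dem(GridSpec(3, 3, cellSize = 30), matrix(c(100, 103), 3, 3))
#' directionalSlope(d, c(1, 1), c(1, 2))
#' @export
directionalSlope <- function(dem, from, to, connectivity = 8L) {
  dr <- to[1] - from[1]; dc <- to[2] - from[2]
  off <- neighborOffsets(as.integer(connectivity))
  if (!any(off[, "dr"] == dr & off[, "dc"] == dc))
    stop("cells are not adjacent under ", connectivity, "-connectivity")
  d <- sqrt(dr^2 + dc^2) * dem@grid@cellSize
  (dem@values[to[1], to[2]] - dem@values[from[1], from[2]]) / d
}
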