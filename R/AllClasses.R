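#' @import methods
NULL

#' GridSpec: geometry of a raster lattice
#'
#' Describes a uniform, axis-aligned, georeferenced grid in projected
#' coordinates. \code{originX}/\code{originY} are the coordinates of the
#' lower-left corner of the grid; row 1 is the northernmost row, so the
#' centre of cell (row, col) is at
#' \code{(originX + (col - 0.5) * cellSize, originY + (nRows - row + 0.5) * cellSize)}.
#' All co-registered rasters in one analysis must share an identical GridSpec.
#'
#' @slot nRows,nCols integer grid dimensions (>= 1).
#' @slot cellSize cell edge length in projected metres (> 0).
#' @slot originX,originY projected coordinates of the lower-left corner.
#' @slot crs free-text label of the projected CRS (e.g. "WGS84/UTM 35S").
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer", cellSize = "numeric",
                 originX = "numeric", originY = "numeric", crs = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@nRows) != 1L || object@nRows < 1L)
      msg <- c(msg, "nRows must be a single integer >= 1")
    if (length(object@nCols) != 1L || object@nCols < 1L)
      msg <- c(msg, "nCols must be a single integer >= 1")
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@originX) != 1L || length(object@originY) != 1L ||
        !is.finite(object@originX) || !is.finite(object@originY))
      msg <- c(msg, "origin must be finite coordinates")
    if (length(msg)) msg else TRUE
  })

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSize cell edge in metres (default 30, the nominal analysis
#'   resolution).
#' @param originX,originY lower-left corner coordinates (default 0).
#' @param crs CRS label.
#' @return A \linkS4class{GridSpec}.
#' @examples
#' GridSpec(100, 120)
#' @export
GridSpec <- function(nRows, nCols, cellSize = 30, originX = 0, originY = 0,
                     crs = "WGS84/UTM 35S") {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSize = as.numeric(cellSize), originX = as.numeric(originX),
      originY = as.numeric(originY), crs = as.character(crs))
}

# Virtual parent for all matrix-backed grid layers.
setClass("GridLayer",
  representation(grid = "GridSpec", values = "matrix", "VIRTUAL"),
  validity = function(object) {
    if (nrow(object@values) != object@grid@nRows ||
        ncol(object@values) != object@grid@nCols)
      return("values matrix does not match grid dimensions")
    TRUE
  })

#' ClassRaster: integer-coded land-feature grid
#'
#' A matrix of registered land-class codes on a \linkS4class{GridSpec}.
#' \code{NA} cells are nodata.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot values integer matrix of land-class codes (\code{NA} = nodata).
#' @slot nodataCode integer used to encode nodata on disk.
#' @export
setClass("ClassRaster", contains = "GridLayer",
  representation(nodataCode = "integer"),
  validity = function(object) {
    v <- object@values
    if (!is.integer(v)) return("values must be an integer matrix")
    codes <- unique(v[!is.na(v)])
    bad <- setdiff(codes, landClasses()$code)
    if (length(bad))
      return(paste("unregistered land class code(s):",
                   paste(sort(bad), collapse = ", ")))
    TRUE
  })

#' Construct a ClassRaster
#' @param grid a \linkS4class{GridSpec}.
#' @param values integer matrix of land-class codes (recycled scalar allowed).
#' @param nodataCode integer nodata sentinel for serialization (default -1).
#' @return A \linkS4class{ClassRaster}.
#' @examples
#' g <- GridSpec(5, 5)
#' ClassRaster(g, landClassCode("grassland"))
#' @export
ClassRaster <- function(grid, values, nodataCode = -1L) {
  if (length(values) == 1L)
    values <- matrix(values, grid@nRows, grid@nCols)
  storage.mode(values) <- "integer"
  new("ClassRaster", grid = grid, values = values,
      nodataCode = as.integer(nodataCode))
}

#' Dem: digital elevation model
#'
#' Per-cell terrain elevation in metres above sea level.
#' @slot grid the \linkS4class{GridSpec}.
#' @slot values numeric matrix of elevations; finite on non-nodata cells.
#' @export
setClass("Dem", contains = "GridLayer",
  validity = function(object) {
    if (any(is.infinite(object@values))) return("elevations must be finite")
    TRUE
  })

#' Construct a Dem
#' @param grid a \linkS4class{GridSpec}.
#' @param values numeric elevation matrix (recycled scalar allowed).
#' @return A \linkS4class{Dem}.
#' @export
Dem <- function(grid, values) {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  storage.mode(values) <- "double"
  new("Dem", grid = grid, values = values)
}

#' TravelTimeSurface: minutes to the nearest facility
#'
#' Per-cell minimum travel time (minutes) to the nearest source facility
#' under one travel scenario; \code{NA} marks unreachable cells (barriers
#' and cells with no passable path to any source).
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot values numeric matrix of minutes (>= 0) or \code{NA}.
#' @slot scenarioId scenario label, e.g. "walking" or "all_modes".
#' @export
setClass("TravelTimeSurface", contains = "GridLayer",
  representation(scenarioId = "character"),
  validity = function(object) {
    v <- object@values
    if (any(v[!is.na(v)] < 0)) return("travel times must be non-negative")
    if (length(object@scenarioId) != 1L) return("scenarioId must be scalar")
    TRUE
  })

TravelTimeSurface <- function(grid, values, scenarioId) {
  storage.mode(values) <- "double"
  new("TravelTimeSurface", grid = grid, values = values,
      scenarioId = as.character(scenarioId))
}

#' ZoneRaster: categorical 30-minute travel-time bands
#'
#' Integer codes 1..5 corresponding to \code{zoneLevels()}:
#' 0-30, 31-60, 61-90, 91-120 minutes and over-2-hours (which also absorbs
#' unreachable cells). Zones partition the grid: no nodata.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot values integer matrix in 1..5.
#' @export
setClass("ZoneRaster", contains = "GridLayer",
  validity = function(object) {
    v <- object@values
    if (anyNA(v) || !all(v %in% seq_along(ZONE_LEVELS)))
      return("zone codes must be 1..5 with no nodata")
    TRUE
  })

ZoneRaster <- function(grid, values) {
  storage.mode(values) <- "integer"
  new("ZoneRaster", grid = grid, values = values)
}

#' CatchmentMask: the 2-hour good-access area
#'
#' Logical per-cell indicator of travel time at or under the good-access
#' threshold (120 minutes by default).
#' @slot grid the \linkS4class{GridSpec}.
#' @slot values logical matrix; TRUE = inside the catchment.
#' @export
setClass("CatchmentMask", contains = "GridLayer",
  validity = function(object) {
    if (!is.logical(object@values)) return("mask values must be logical")
    if (anyNA(object@values)) return("mask must have no NA")
    TRUE
  })

CatchmentMask <- function(grid, values) {
  storage.mode(values) <- "logical"
  new("CatchmentMask", grid = grid, values = values)
}

#' BirthRaster: gridded expected live-birth counts
#'
#' Non-negative expected live births per cell, usually on its own (coarser)
#' grid than the travel-time analysis — nominally 100 m cells versus the
#' 30 m analysis lattice. It is never resampled; zonal statistics assign
#' each birth cell by its centre.
#'
#' @slot grid the \linkS4class{GridSpec} of the birth lattice.
#' @slot values numeric matrix of expected births (>= 0; NA = nodata).
#' @export
setClass("BirthRaster", contains = "GridLayer",
  validity = function(object) {
    v <- object@values
    if (any(v[!is.na(v)] < 0)) return("birth counts must be non-negative")
    if (!is.finite(sum(v, na.rm = TRUE))) return("total births must be finite")
    TRUE
  })

#' Construct a BirthRaster
#' @param grid a \linkS4class{GridSpec} (nominally 100 m cells).
#' @param values numeric matrix of expected live births per cell.
#' @return A \linkS4class{BirthRaster}.
#' @export
BirthRaster <- function(grid, values) {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  storage.mode(values) <- "double"
  new("BirthRaster", grid = grid, values = values)
}

#' AdminUnits: administrative council partition
#'
#' A labelled partition of the analysis grid into administrative units,
#' with optional source polygons. The per-cell label matrix is the working
#' representation (0 = outside every unit); polygons, when supplied, are
#' rasterized once by the cell-centre rule.
#'
#' @slot grid the analysis \linkS4class{GridSpec}.
#' @slot values integer matrix of unit indices (0 = none).
#' @slot unitNames character vector; \code{values == i} belongs to
#'   \code{unitNames[i]}.
#' @slot polygons optional \linkS4class{VectorLayer} of unit polygons.
#' @export
setClass("AdminUnits", contains = "GridLayer",
  representation(unitNames = "character", polygons = "ANY"),
  validity = function(object) {
    v <- object@values
    if (anyNA(v) || any(v < 0L) || any(v > length(object@unitNames)))
      return("unit labels must be 0..length(unitNames) with no NA")
    if (anyDuplicated(object@unitNames)) return("unit names must be unique")
    TRUE
  })

#' VectorLayer: simple feature collection
#'
#' A minimal vector data container: a list of features, each a list with a
#' two-column coordinate matrix \code{coords} (projected x, y) and a
#' character \code{class} tag (a land-class name or other attribute).
#' Polygon rings are closed implicitly (last vertex need not repeat the
#' first).
#'
#' @slot geometryKind one of "polyline", "polygon", "point".
#' @slot features list of \code{list(coords = matrix, class = character)}.
#' @slot crs CRS label; must match the grid it is rasterized onto.
#' @export
setClass("VectorLayer",
  representation(geometryKind = "character", features = "list",
                 crs = "character"),
  validity = function(object) {
    if (!object@geometryKind %in% c("polyline", "polygon", "point"))
      return("geometryKind must be polyline, polygon or point")
    ok <- vapply(object@features, function(f) {
      is.list(f) && is.matrix(f$coords) && ncol(f$coords) == 2L &&
        nrow(f$coords) >= 1L && !is.null(f$class)
    }, logical(1))
    if (!all(ok)) return("each feature needs a 2-column coords matrix and a class tag")
    TRUE
  })

#' Construct a VectorLayer
#' @param geometryKind "polyline", "polygon" or "point".
#' @param features list of \code{list(coords, class)} features.
#' @param crs CRS label.
#' @return A \linkS4class{VectorLayer}.
#' @export
VectorLayer <- function(geometryKind, features = list(),
                        crs = "WGS84/UTM 35S") {
  features <- lapply(features, function(f) {
    f$coords <- matrix(as.numeric(f$coords), ncol = 2,
                       dimnames = list(NULL, c("x", "y")))
    f
  })
  new("VectorLayer", geometryKind = geometryKind, features = features,
      crs = crs)
}

#' ToblerParams: anisotropic walking-speed correction
#'
#' Parameters of the exponential hiking-speed model
#' \code{v(slope) = v_flat * exp(-steepness * |slope + offset|) / norm}.
#' With \code{normalizeToFlat = TRUE} (default) the multiplier is anchored
#' at exactly 1 on flat ground, so land-cover walking speeds are treated as
#' flat-terrain speeds that the slope modulates; with it off, the raw
#' exponential is used (classic absolute form) and the speed maximum sits at
#' a gentle downhill slope of \code{-offset}.
#'
#' @slot steepness exponential decay rate per unit slope (default 3.5).
#' @slot offset slope of maximum speed, negated (default 0.05).
#' @slot normalizeToFlat logical, anchor the factor to 1 at slope 0.
#' @export
setClass("ToblerParams",
  representation(steepness = "numeric", offset = "numeric",
                 normalizeToFlat = "logical"),
  validity = function(object) {
    if (object@steepness <= 0) return("steepness must be > 0")
    if (object@offset < 0 || object@offset >= 1)
      return("offset must be in [0, 1)")
    TRUE
  })

#' Construct ToblerParams
#' @param steepness decay rate (default 3.5).
#' @param offset slope offset (default 0.05).
#' @param normalizeToFlat anchor multiplier to 1 on flat ground (default TRUE).
#' @return A \linkS4class{ToblerParams}.
#' @examples
#' ToblerParams()
#' @export
ToblerParams <- function(steepness = 3.5, offset = 0.05,
                         normalizeToFlat = TRUE) {
  new("ToblerParams", steepness = as.numeric(steepness),
      offset = as.numeric(offset),
      normalizeToFlat = as.logical(normalizeToFlat))
}

#' EngineConfig: least-cost accumulation options
#'
#' @slot connectivity 8 (queen moves) or 16 (queen plus knight moves).
#' @export
setClass("EngineConfig",
  representation(connectivity = "integer"),
  validity = function(object) {
    if (!object@connectivity %in% c(8L, 16L))
      return("connectivity must be 8 or 16")
    TRUE
  })

#' Construct an EngineConfig
#' @param connectivity 8 (default) or 16 neighbours.
#' @return An \linkS4class{EngineConfig}.
#' @export
EngineConfig <- function(connectivity = 8) {
  new("EngineConfig", connectivity = as.integer(connectivity))
}

#' SpeedTable: per-scenario land-class speeds
#'
#' Maps every registered land class to a transport mode and a speed in
#' km/h, or flags it impassable. Barrier classes (wetland, river cells,
#' open water) are impassable in every scenario; the boat route carries
#' boat travel at the same speed in all scenarios.
#'
#' @slot scenarioId one of "walking", "cycling", "motorcycle", "car" (or a
#'   user label for custom tables).
#' @slot entries data.frame with columns \code{class} (land-class name),
#'   \code{mode} (transport mode, NA if impassable) and \code{speed_kmh}
#'   (NA if impassable).
#' @export
setClass("SpeedTable",
  representation(scenarioId = "character", entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    need <- c("class", "mode", "speed_kmh")
    if (!all(need %in% names(e))) return("entries needs class/mode/speed_kmh")
    lc <- landClasses()
    if (!setequal(e$class, lc$name) || anyDuplicated(e$class))
      return("entries must cover every registered land class exactly once")
    passable <- !is.na(e$mode)
    if (any(is.na(e$speed_kmh[passable])) ||
        any(e$speed_kmh[passable] <= 0))
      return("passable entries need a finite positive speed")
    if (!all(is.na(e$speed_kmh[!passable])))
      return("impassable entries must have NA speed")
    badmode <- setdiff(e$mode[passable], transportModes()$name)
    if (length(badmode))
      return(paste("unknown transport mode(s):", paste(badmode, collapse = ", ")))
    barr <- lc$name[lc$barrier]
    if (any(passable[match(barr, e$class)]))
      return("barrier classes (wetland/river/water) must be impassable")
    TRUE
  })

#' Construct a SpeedTable
#' @param scenarioId scenario label.
#' @param entries data.frame with columns class, mode, speed_kmh.
#' @return A \linkS4class{SpeedTable}.
#' @seealso \code{\link{defaultSpeedTable}} for the packaged scenario tables.
#' @export
SpeedTable <- function(scenarioId, entries) {
  entries$class <- as.character(entries$class)
  entries$mode <- as.character(entries$mode)
  entries$speed_kmh <- as.numeric(entries$speed_kmh)
  rownames(entries) <- NULL
  new("SpeedTable", scenarioId = as.character(scenarioId),
      entries = entries[order(match(entries$class, landClasses()$name)),
                        c("class", "mode", "speed_kmh")])
}

#' SyntheticRegion: one generated study landscape
#'
#' Bundle of co-registered synthetic inputs produced by
#' \code{\link{simulateRegion}}: combined-ready land cover, DEM, network
#' vectors, facilities, births, councils, plus the generating parameters
#' for provenance.
#'
#' @slot landcover \linkS4class{ClassRaster} (base cover, roads not burnt).
#' @slot dem \linkS4class{Dem}.
#' @slot roads,rivers,boatRoutes \linkS4class{VectorLayer} polylines.
#' @slot facilities data.frame (id, x, y, care_level, is_emonc).
#' @slot births \linkS4class{BirthRaster} on its own 100 m lattice.
#' @slot councils \linkS4class{AdminUnits}.
#' @slot combined \linkS4class{ClassRaster} after burning rivers, roads and
#'   boat routes.
#' @slot params the generating \code{LandscapeParams} list (includes seed).
#' @export
setClass("SyntheticRegion",
  representation(landcover = "ClassRaster", dem = "Dem",
                 roads = "VectorLayer", rivers = "VectorLayer",
                 boatRoutes = "VectorLayer", facilities = "data.frame",
                 births = "BirthRaster", councils = "AdminUnits",
                 combined = "ClassRaster", params = "list"))
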