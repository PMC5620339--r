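#' @include AllClasses.R
NULL

#' Accessors for grid layers
#'
#' \code{gridSpec} returns the \linkS4class{GridSpec} of a layer;
#' \code{gridValues} its backing matrix; \code{nRows}, \code{nCols} and
#' \code{cellSize} the corresponding GridSpec fields; \code{scenarioId} the
#' scenario label of a \linkS4class{TravelTimeSurface} or
#' \linkS4class{SpeedTable}.
#'
#' @param x a grid layer, GridSpec, surface or speed table.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))
#' @rdname accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("scenarioId", function(x) standardGeneric("scenarioId"))
#' @rdname accessors
#' @export
setGeneric("speedEntries", function(x) standardGeneric("speedEntries"))
#' @rdname accessors
#' @export
setGeneric("unitNames", function(x) standardGeneric("unitNames"))

#' @rdname accessors
setMethod("gridSpec", "GridLayer", function(x) x@grid)
#' @rdname accessors
setMethod("gridValues", "GridLayer", function(x) x@values)
#' @rdname accessors
setMethod("nRows", "GridSpec", function(x) x@nRows)
#' @rdname accessors
setMethod("nCols", "GridSpec", function(x) x@nCols)
#' @rdname accessors
setMethod("cellSize", "GridSpec", function(x) x@cellSize)
#' @rdname accessors
setMethod("nRows", "GridLayer", function(x) x@grid@nRows)
#' @rdname accessors
setMethod("nCols", "GridLayer", function(x) x@grid@nCols)
#' @rdname accessors
setMethod("cellSize", "GridLayer", function(x) x@grid@cellSize)
#' @rdname accessors
setMethod("scenarioId", "TravelTimeSurface", function(x) x@scenarioId)
#' @rdname accessors
setMethod("scenarioId", "SpeedTable", function(x) x@scenarioId)
#' @rdname accessors
setMethod("speedEntries", "SpeedTable", function(x) x@entries)
#' @rdname accessors
setMethod("unitNames", "AdminUnits", function(x) x@unitNames)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g), CRS %s\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY, object@crs))
})

setMethod("show", "GridLayer", function(object) {
  v <- object@values
  cat(sprintf("%s on %d x %d grid (%g m cells); %d nodata cell(s)\n",
              class(object), nrow(v), ncol(v), object@grid@cellSize,
              sum(is.na(v))))
  if (is.numeric(v) && any(!is.na(v)))
    cat(sprintf("  value range: [%g, %g]\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "TravelTimeSurface", function(object) {
  v <- object@values
  reach <- !is.na(v)
  cat(sprintf("TravelTimeSurface (%s): %d x %d cells, %.1f%% reachable",
              object@scenarioId, nrow(v), ncol(v), 100 * mean(reach)))
  if (any(reach))
    cat(sprintf(", minutes in [%.2f, %.2f]", min(v[reach]), max(v[reach])))
  cat("\n")
})

setMethod("show", "SpeedTable", function(object) {
  cat(sprintf("SpeedTable '%s':\n", object@scenarioId))
  e <- object@entries
  e$speed <- ifelse(is.na(e$mode), "impassable",
                    sprintf("%s %.1f km/h", e$mode, e$speed_kmh))
  print(e[, c("class", "speed")], row.names = FALSE)
})

setMethod("show", "VectorLayer", function(object) {
  cat(sprintf("VectorLayer: %d %s feature(s), classes: %s\n",
              length(object@features), object@geometryKind,
              paste(unique(vapply(object@features, `[[`, "", "class")),
                    collapse = ", ")))
})

setMethod("show", "AdminUnits", function(object) {
  cat(sprintf("AdminUnits: %d unit(s) on %d x %d grid: %s\n",
              length(object@unitNames), nrow(object@values),
              ncol(object@values),
              paste(object@unitNames, collapse = ", ")))
})

setMethod("show", "SyntheticRegion", function(object) {
  cat(sprintf(
    "SyntheticRegion: %d x %d landscape, %d facilities (%d EmONC), %g births, seed %s\n",
    nRows(object@landcover), nCols(object@landcover),
    nrow(object@facilities), sum(object@facilities$is_emonc),
    sum(object@births@values, na.rm = TRUE),
    format(object@params$seed)))
})
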