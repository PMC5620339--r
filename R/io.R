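#' Write a grid layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster with the standard 6-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value). Integer-valued
#' layers (class, zone, unit rasters) are written as integers, others as
#' floats. Row 1 of the matrix is the northernmost row, matching the
#' format's row order.
#'
#' @param layer any \linkS4class{GridLayer}.
#' @param path output file path.
#' @param digits significant digits for float layers (default 10).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(layer, path, digits = 10) {
  g <- layer@grid
  v <- layer@values
  isInt <- is.integer(v) || is.logical(v)
  nodata <- if (is(layer, "ClassRaster")) layer@nodataCode else -9999L
  hdr <- c(
    paste("ncols", g@nCols),
    paste("nrows", g@nRows),
    paste("xllcorner", format(g@originX, digits = 15)),
    paste("yllcorner", format(g@originY, digits = 15)),
    paste("cellsize", format(g@cellSize, digits = 15)),
    paste("NODATA_value", nodata))
  if (is.logical(v)) v <- matrix(as.integer(v), nrow(v), ncol(v))
  body <- apply(v, 1, function(rw) {
    rw <- if (isInt) ifelse(is.na(rw), nodata, rw)
    else ifelse(is.na(rw), nodata, format(rw, digits = digits,
                                          scientific = FALSE, trim = TRUE))
    paste(rw, collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param as what to construct: "class" (\linkS4class{ClassRaster},
#'   validated against the registered codes), "dem", "births", "surface"
#'   (with \code{scenarioId}) or "zones".
#' @param scenarioId scenario label when \code{as = "surface"}.
#' @param crs CRS label to attach.
#' @return The corresponding grid layer object.
#' @export
readAsciiGrid <- function(path, as = c("class", "dem", "births", "surface",
                                       "zones"),
                          scenarioId = "unknown", crs = "WGS84/UTM 35S") {
  as <- match.arg(as)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  hv <- stats::setNames(vapply(hdr, `[`, "", 2),
                        tolower(vapply(hdr, `[`, "", 1)))
  nc <- as.integer(hv["ncols"]); nr <- as.integer(hv["nrows"])
  nodata <- as.numeric(hv["nodata_value"])
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values; expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  grid <- GridSpec(nr, nc, as.numeric(hv["cellsize"]),
                   as.numeric(hv["xllcorner"]), as.numeric(hv["yllcorner"]),
                   crs)
  switch(as,
    class = {
      codes <- unique(m[!is.na(m)])
      bad <- setdiff(codes, landClasses()$code)
      if (length(bad))
        stop("unknown land class code(s) in ", path, ": ",
             paste(sort(bad), collapse = ", "))
      ClassRaster(grid, m, as.integer(nodata))
    },
    dem = Dem(grid, m),
    births = BirthRaster(grid, m),
    surface = TravelTimeSurface(grid, m, scenarioId),
    zones = ZoneRaster(grid, m))
}

#' Write a vector layer as GeoJSON
#'
#' One Feature per geometry with its \code{class} tag as a property.
#' Polyline features become LineStrings, polygons single-ring Polygons
#' (closed automatically), points Points.
#'
#' @param layer a \linkS4class{VectorLayer}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeoJSON <- function(layer, path) {
  gtype <- switch(layer@geometryKind, polyline = "LineString",
                  polygon = "Polygon", point = "Point")
  feats <- lapply(layer@features, function(f) {
    coords <- unname(f$coords)
    geom <- switch(layer@geometryKind,
      point = list(type = gtype, coordinates = as.numeric(coords[1, ])),
      polyline = list(type = gtype,
                      coordinates = lapply(seq_len(nrow(coords)),
                                           function(i) as.numeric(coords[i, ]))),
      polygon = {
        ring <- coords
        if (!all(ring[1, ] == ring[nrow(ring), ]))
          ring <- rbind(ring, ring[1, ])
        list(type = gtype,
             coordinates = list(lapply(seq_len(nrow(ring)),
                                       function(i) as.numeric(ring[i, ]))))
      })
    list(type = "Feature", geometry = geom,
         properties = list(class = f$class))
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = layer@crs)),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON file written by \code{\link{writeGeoJSON}}
#' @param path file path.
#' @return A \linkS4class{VectorLayer}.
#' @export
readGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  crs <- tryCatch(obj$crs$properties$name, error = function(e) "unknown")
  if (is.null(crs)) crs <- "unknown"
  kind <- switch(obj$features[[1]]$geometry$type,
                 LineString = "polyline", Polygon = "polygon",
                 Point = "point")
  feats <- lapply(obj$features, function(f) {
    co <- f$geometry$coordinates
    coords <- switch(kind,
      point = matrix(unlist(co), ncol = 2),
      polyline = do.call(rbind, lapply(co, unlist)),
      polygon = do.call(rbind, lapply(co[[1]], unlist)))
    list(coords = coords, class = f$properties$class)
  })
  VectorLayer(kind, feats, crs)
}

#' Write / read a facility table as CSV
#' @param facilities data.frame (id, x, y, care_level, is_emonc).
#' @param path file path.
#' @return The path / the facility data.frame.
#' @export
writeFacilities <- function(facilities, path) {
  utils::write.csv(facilities, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFacilities
#' @export
readFacilities <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "care_level")
  if (!all(need %in% names(f)))
    stop("facility CSV needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(f$care_level, CARE_LEVELS)
  if (length(bad)) stop("unknown care level(s): ", paste(bad, collapse = ", "))
  if (is.null(f$is_emonc)) f$is_emonc <- f$care_level != "non_EmONC"
  f
}

#' Run the full accessibility pipeline on a region
#'
#' For each travel scenario: accumulate the travel-time surface from the
#' EmONC facilities, classify 30-minute zones and the 2-hour catchment, and
#' aggregate birth counts and proportions per zone. Then the all-modes
#' surface (cell-wise minimum), the mode-combination map, and per-council
#' poor-access proportions for every scenario including all-modes. All
#' artifacts are written under \code{outDir} as ASCII grids / CSV / JSON
#' with provenance (parameters, seed, package version); outputs are
#' deterministic, so reruns on identical inputs are byte-identical.
#'
#' @param region a \linkS4class{SyntheticRegion} (or any object bundle with
#'   the same slots).
#' @param scenarios scenario ids to run (default all four).
#' @param breaks zone breaks in minutes; the last break is the good-access
#'   threshold.
#' @param outDir output directory, or \code{NULL} to skip writing.
#' @param config,params engine options.
#' @return Invisibly, the summary list (also serialized to
#'   \code{summary.json}): per-scenario zone counts/proportions, per-council
#'   poor-access proportions, and a scenario-dominance audit.
#' @export
runPipeline <- function(region, scenarios = scenarioIds(),
                        breaks = c(30, 60, 90, 120), outDir = NULL,
                        config = EngineConfig(), params = ToblerParams()) {
  if (length(scenarios) == 0L) stop("scenario list must be non-empty")
  threshold <- breaks[length(breaks)]
  combined <- region@combined
  emonc <- region@facilities[region@facilities$is_emonc, , drop = FALSE]
  if (nrow(emonc) == 0L) stop("no EmONC facility in the region")
  sources <- snapFacilities(emonc, combined)

  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  surfaces <- list()
  perZone <- list()
  perCouncil <- list()
  for (sc in scenarios) {
    surf <- accumulateTravelTime(combined, region@dem, defaultSpeedTable(sc),
                                 sources, config = config, params = params)
    surfaces[[sc]] <- surf
    zones <- classifyZones(surf, breaks)
    counts <- zonalBirthCounts(zones, region@births)
    props <- proportionPerZone(counts)
    perZone[[sc]] <- list(births = as.list(round(counts, 6)),
                          proportion = as.list(round(props, 10)))
    perCouncil[[sc]] <- as.list(round(
      poorAccessByUnit(surf, region@births, region@councils, threshold), 10))
    if (!is.null(outDir)) {
      writeAsciiGrid(surf, file.path(outDir, paste0("travel_time_", sc, ".asc")))
      writeAsciiGrid(zones, file.path(outDir, paste0("zones_", sc, ".asc")))
      writeAsciiGrid(twoHourCatchment(surf, threshold),
                     file.path(outDir, paste0("catchment_", sc, ".asc")))
      df <- data.frame(zone = ZONE_LEVELS, births = round(counts, 6),
                       proportion = round(props, 10))
      utils::write.csv(df, file.path(outDir, paste0("coverage_", sc, ".csv")),
                       row.names = FALSE)
    }
  }

  allModes <- allModesMinimum(surfaces)
  amZones <- classifyZones(allModes, breaks)
  amCounts <- zonalBirthCounts(amZones, region@births)
  perZone[["all_modes"]] <- list(
    births = as.list(round(amCounts, 6)),
    proportion = as.list(round(proportionPerZone(amCounts), 10)))
  perCouncil[["all_modes"]] <- as.list(round(
    poorAccessByUnit(allModes, region@births, region@councils, threshold), 10))
  combo <- modeCombinationMap(surfaces, threshold)

  poorRegional <- vapply(names(perZone), function(sc)
    perZone[[sc]]$proportion$OVER_120, numeric(1))
  audit <- list(
    walking_ge_cycling = poorRegional[["walking"]] >= poorRegional[["cycling"]],
    cycling_ge_motorcycle =
      poorRegional[["cycling"]] >= poorRegional[["motorcycle"]],
    walking_ge_car = poorRegional[["walking"]] >= poorRegional[["car"]],
    all_modes_le_all = all(poorRegional[["all_modes"]] <=
                             poorRegional[setdiff(names(poorRegional),
                                                  "all_modes")]))

  summary <- list(
    provenance = list(package = "accesscape",
                      version = as.character(utils::packageVersion("accesscape")),
                      seed = region@params$seed,
                      scenarios = scenarios,
                      breaks = breaks, threshold_minutes = threshold),
    zones = perZone,
    poor_access_by_council = perCouncil,
    poor_access_regional = as.list(round(poorRegional, 10)),
    dominance_audit = audit)

  if (!is.null(outDir)) {
    writeAsciiGrid(allModes, file.path(outDir, "travel_time_all_modes.asc"))
    # mode-combination bitmask written as a plain integer grid
    writeLines(c(paste("ncols", combined@grid@nCols),
                 paste("nrows", combined@grid@nRows),
                 paste("xllcorner", format(combined@grid@originX, digits = 15)),
                 paste("yllcorner", format(combined@grid@originY, digits = 15)),
                 paste("cellsize", format(combined@grid@cellSize, digits = 15)),
                 "NODATA_value -1",
                 apply(combo$mask, 1, paste, collapse = " ")),
               file.path(outDir, "mode_combination.asc"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(summary, list(surfaces = surfaces, combo = combo)))
}
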