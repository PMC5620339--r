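#' Transport modes
#'
#' The five transport modes used across the four travel scenarios. Only
#' walking is slope-corrected (anisotropic): motorized transport needs no
#' directional adjustment, and bicycling is deliberately isotropic by
#' default, mirroring a known limitation of the original accessibility
#' software (see \code{\link{effectiveSpeed}} for the opt-in override).
#'
#' @return data.frame with columns \code{name} and \code{anisotropic}.
#' @export
transportModes <- function() {
  data.frame(
    name = c("walking", "bicycle", "motorcycle", "car", "boat"),
    anisotropic = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Scenario identifiers
#' @return Character vector of the four travel scenario ids.
#' @export
scenarioIds <- function() c("walking", "cycling", "motorcycle", "car")

# speed table rows as (mode, speed); NA = impassable
.speedRow <- function(mode, speed) list(mode = mode, speed = speed)

#' Default per-scenario speed tables
#'
#' Returns the packaged dry-season speed table for one of the four travel
#' scenarios. Each scenario pairs one primary transport mode with walking
#' (everyone walks off-road) and boat travel (15 km/h along boat routes in
#' every scenario). Wetlands, river cells and open water are impassable to
#' every mode. Off-road cycling and motorcycling at 7 km/h reflect reduced
#' vehicle speed on low-density vegetation and built areas; walking
#' speeds are halved urban walking speeds approximating a pregnant woman
#' walking or being carried on a stretcher.
#'
#' @param scenarioId one of \code{scenarioIds()}.
#' @return A \linkS4class{SpeedTable}.
#' @examples
#' defaultSpeedTable("car")
#' @export
defaultSpeedTable <- function(scenarioId) {
  if (!scenarioId %in% scenarioIds())
    stop("unknown scenario '", scenarioId, "'; valid: ",
         paste(scenarioIds(), collapse = ", "))
  # class -> c(mode, speed_kmh); NA row = impassable
  spec <- switch(scenarioId,
    walking = list(
      forestland = c("walking", 1.0), grassland = c("walking", 1.7),
      cropland = c("walking", 1.7), settlement = c("walking", 2.5),
      other_land = c("walking", 2.5), boat_route = c("boat", 15.0),
      major_road = c("walking", 2.5), major_road_residential = c("walking", 2.5),
      secondary_road = c("walking", 2.5), local_road_all = c("walking", 2.5),
      local_road_moto_bike = c("walking", 2.5), local_road_walk = c("walking", 2.5)),
    cycling = list(
      forestland = c("walking", 1.0), grassland = c("bicycle", 7.0),
      cropland = c("walking", 1.7), settlement = c("bicycle", 7.0),
      other_land = c("bicycle", 7.0), boat_route = c("boat", 15.0),
      major_road = c("bicycle", 10.0), major_road_residential = c("bicycle", 10.0),
      secondary_road = c("bicycle", 10.0), local_road_all = c("bicycle", 10.0),
      local_road_moto_bike = c("bicycle", 10.0), local_road_walk = c("walking", 2.5)),
    motorcycle = list(
      forestland = c("walking", 1.0), grassland = c("motorcycle", 7.0),
      cropland = c("walking", 1.7), settlement = c("motorcycle", 7.0),
      other_land = c("motorcycle", 7.0), boat_route = c("boat", 15.0),
      major_road = c("motorcycle", 40.2), major_road_residential = c("motorcycle", 26.2),
      secondary_road = c("motorcycle", 35.2), local_road_all = c("motorcycle", 15.0),
      local_road_moto_bike = c("motorcycle", 15.0), local_road_walk = c("walking", 2.5)),
    car = list(
      forestland = c("walking", 1.0), grassland = c("walking", 1.7),
      cropland = c("walking", 1.7), settlement = c("walking", 2.5),
      other_land = c("walking", 2.5), boat_route = c("boat", 15.0),
      major_road = c("car", 50.0), major_road_residential = c("car", 30.0),
      secondary_road = c("car", 40.0), local_road_all = c("car", 15.0),
      local_road_moto_bike = c("walking", 2.5), local_road_walk = c("walking", 2.5))
  )
  lc <- landClasses()
  entries <- data.frame(class = lc$name, mode = NA_character_,
                        speed_kmh = NA_real_, stringsAsFactors = FALSE)
  for (cls in names(spec)) {
    i <- match(cls, entries$class)
    entries$mode[i] <- spec[[cls]][1]
    entries$speed_kmh[i] <- as.numeric(spec[[cls]][2])
  }
  # barrier classes (wetland, river_barrier, water) stay impassable
  SpeedTable(scenarioId, entries)
}

#' Tobler slope multiplier for walking speed
#'
#' Exponential slope correction of walking speed:
#' \code{exp(-steepness * |slope + offset|)}, divided by its flat-ground
#' value \code{exp(-steepness * offset)} when \code{normalizeToFlat}, so
#' that the factor is exactly 1 on flat terrain. The factor peaks at a
#' gentle downhill slope of \code{-offset} and decays symmetrically about
#' it.
#'
#' @param slope dimensionless rise-over-run (vectorized), positive uphill.
#' @param params a \linkS4class{ToblerParams}.
#' @return Positive multiplier(s) applied to the flat walking speed.
#' @examples
#' toblerMultiplier(0)          # exactly 1
#' toblerMultiplier(c(-0.1, 0.1))
#' @export
toblerMultiplier <- function(slope, params = ToblerParams()) {
  f <- exp(-params@steepness * abs(slope + params@offset))
  if (params@normalizeToFlat)
    f <- f / exp(-params@steepness * params@offset)
  f
}

#' Effective speed of one cell under a scenario entry
#'
#' Applies the anisotropic correction where it belongs: walking speed is
#' multiplied by \code{\link{toblerMultiplier}} of the slope in the
#' direction of travel; bicycle, motorcycle, car and boat speeds pass
#' through unchanged. Setting \code{anisotropicBicycle = TRUE} additionally
#' slope-corrects bicycle speed (off by default, reproducing the original
#' software's isotropic-bicycle behaviour; useful for sensitivity
#' analysis).
#'
#' @param mode transport mode name, or NA for an impassable entry.
#' @param speedKmh flat speed in km/h (NA if impassable).
#' @param slope directional slope (dimensionless).
#' @param params \linkS4class{ToblerParams}.
#' @param anisotropicBicycle also slope-correct bicycle speed.
#' @return Speed in km/h, or NA for impassable entries.
#' @export
effectiveSpeed <- function(mode, speedKmh, slope, params = ToblerParams(),
                           anisotropicBicycle = FALSE) {
  if (is.na(mode) || is.na(speedKmh)) return(NA_real_)
  aniso <- mode == "walking" || (anisotropicBicycle && mode == "bicycle")
  if (aniso) speedKmh * toblerMultiplier(slope, params) else speedKmh
}

#' Write / read speed tables as YAML
#'
#' Serializes one or more speed tables to a YAML config mapping
#' \code{scenario -> {land_class: {mode, speed_kmh}}}, with the literal
#' token \code{impassable} for barrier entries. Round-trips exactly.
#'
#' @param tables a \linkS4class{SpeedTable} or list of them.
#' @param path file path.
#' @return \code{readSpeedTables} returns a named list of
#'   \linkS4class{SpeedTable}s; \code{writeSpeedTables} returns \code{path}
#'   invisibly.
#' @export
writeSpeedTables <- function(tables, path) {
  if (is(tables, "SpeedTable")) tables <- list(tables)
  out <- list()
  for (st in tables) {
    e <- st@entries
    ent <- list()
    for (i in seq_len(nrow(e))) {
      ent[[e$class[i]]] <- if (is.na(e$mode[i])) "impassable" else
        list(mode = e$mode[i], speed_kmh = e$speed_kmh[i])
    }
    out[[st@scenarioId]] <- ent
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname writeSpeedTables
#' @export
readSpeedTables <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(stats::setNames(names(raw), names(raw)), function(sc) {
    ent <- raw[[sc]]
    entries <- data.frame(class = names(ent), mode = NA_character_,
                          speed_kmh = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(ent)) {
      if (!identical(ent[[i]], "impassable")) {
        entries$mode[i] <- ent[[i]]$mode
        entries$speed_kmh[i] <- ent[[i]]$speed_kmh
      }
    }
    SpeedTable(sc, entries)
  })
}
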