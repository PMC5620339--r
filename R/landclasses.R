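#' Registered land-feature classes
#'
#' The combined land-cover raster distinguishes 13 user-facing land feature
#' classes: six non-road cover classes (forestland, grassland, cropland,
#' settlement, wetland, other land), six road classes and the boat route.
#' Two further codes are internal: \code{river_barrier} preserves the
#' provenance of burnt-in river cells (they behave exactly like wetland:
#' impassable in every scenario), and \code{water} codes open lake water,
#' which is likewise impassable everywhere except along burnt boat routes.
#'
#' @return A data.frame with columns \code{code} (integer), \code{name},
#'   \code{barrier} (impassable in every scenario) and \code{road}.
#' @examples
#' landClasses()
#' @export
landClasses <- function() {
  data.frame(
    code = 1:15,
    name = c("forestland", "grassland", "cropland", "settlement", "wetland",
             "other_land", "river_barrier", "boat_route", "major_road",
             "major_road_residential", "secondary_road", "local_road_all",
             "local_road_moto_bike", "local_road_walk", "water"),
    barrier = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                FALSE, TRUE, FALSE, FALSE,
                FALSE, FALSE, FALSE,
                FALSE, FALSE, TRUE),
    road = c(FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE, FALSE, TRUE,
             TRUE, TRUE, TRUE,
             TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Look up a land-class code by name
#'
#' @param name Character vector of registered class names.
#' @return Integer vector of class codes.
#' @examples
#' landClassCode(c("grassland", "major_road"))
#' @export
landClassCode <- function(name) {
  lc <- landClasses()
  idx <- match(name, lc$name)
  if (anyNA(idx)) {
    stop("unknown land class name(s): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  lc$code[idx]
}

#' Land-class name for a code
#' @param code Integer vector of registered class codes.
#' @return Character vector of names.
#' @export
landClassName <- function(code) {
  lc <- landClasses()
  idx <- match(code, lc$code)
  if (anyNA(idx)) {
    stop("unknown land class code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  lc$name[idx]
}

#' Codes of classes impassable under every travel scenario
#' @return Integer vector (wetland, river_barrier, water).
#' @export
barrierCodes <- function() {
  lc <- landClasses()
  lc$code[lc$barrier]
}

# Travel-time zone labels, in band order. OVER_120 doubles as the
# unreachable category.
ZONE_LEVELS <- c("Z0_30", "Z31_60", "Z61_90", "Z91_120", "OVER_120")

#' Travel-time zone labels
#'
#' Band labels for the four incremental 30-minute zones up to the 2-hour
#' good-access threshold, plus the over-2-hours / unreachable category.
#' @return Character vector of the five zone labels in band order.
#' @export
zoneLevels <- function() ZONE_LEVELS

# EmONC care levels; the first three count as EmONC service providers.
CARE_LEVELS <- c("CEmONC", "CEmONC_minus_1", "BEmONC_minus_1", "non_EmONC")

#' Facility care levels
#' @return Character vector of recognised care levels; all but
#'   \code{non_EmONC} provide EmONC care.
#' @export
careLevels <- function() CARE_LEVELS
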