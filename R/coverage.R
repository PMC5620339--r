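# Map birth cells onto an analysis grid by their centres (the birth raster
# is never resampled). Returns parallel vectors: births per birth cell and
# the linear index of the containing analysis cell (NA when outside).
birthCellLookup <- function(births, grid) {
  bg <- births@grid
  idx <- expand.grid(row = seq_len(bg@nRows), col = seq_len(bg@nCols))
  w <- births@values[cbind(idx$row, idx$col)]
  keep <- !is.na(w) & w != 0
  idx <- idx[keep, , drop = FALSE]
  w <- w[keep]
  ctr <- cellCenter(bg, idx$row, idx$col)
  rc <- xyToCell(grid, ctr[, 1], ctr[, 2])
  cell <- ifelse(is.na(rc$row), NA_integer_,
                 rc$row + grid@nRows * (rc$col - 1L))
  list(births = w, cell = cell)
}

#' Zonal birth counts
#'
#' Aggregates the birth raster over travel-time zones: every birth cell is
#' assigned, by its centre, to the zone of the containing zone-raster cell
#' (nearest-neighbour lookup across the two resolutions — the birth raster
#' is never resampled). Counts conserve the raster total exactly; birth
#' cells whose centres fall outside the zone grid are counted in the
#' over-threshold band with a warning.
#'
#' @param zones a \linkS4class{ZoneRaster}.
#' @param births a \linkS4class{BirthRaster} (possibly different
#'   resolution).
#' @return Named numeric vector of birth counts, one per
#'   \code{zoneLevels()}.
#' @export
zonalBirthCounts <- function(zones, births) {
  lk <- birthCellLookup(births, zones@grid)
  zone <- rep(match("OVER_120", ZONE_LEVELS), length(lk$cell))
  inGrid <- !is.na(lk$cell)
  if (any(!inGrid))
    warning(sum(!inGrid), " birth cell(s) outside the zone grid assigned ",
            "to OVER_120")
  zone[inGrid] <- zones@values[lk$cell[inGrid]]
  counts <- vapply(seq_along(ZONE_LEVELS),
                   function(z) sum(lk$births[zone == z]), numeric(1))
  stats::setNames(counts, ZONE_LEVELS)
}

#' Per-zone birth proportions
#'
#' @param counts named per-zone birth counts (from
#'   \code{\link{zonalBirthCounts}}).
#' @return Named proportions summing to 1.
#' @export
proportionPerZone <- function(counts) {
  total <- sum(counts)
  if (!is.finite(total) || total <= 0)
    stop("total births must be positive to form proportions")
  counts / total
}

#' Proportion of births with poor access, per administrative unit
#'
#' For each council, the share of its births located at cells with travel
#' time over the good-access threshold (or unreachable). Births are
#' assigned to councils and to access status by birth-cell centre lookup.
#' Councils containing no births get \code{NA}, not 0.
#'
#' @param surface a \linkS4class{TravelTimeSurface} on the analysis grid.
#' @param births a \linkS4class{BirthRaster}.
#' @param units an \linkS4class{AdminUnits} partition of the analysis grid.
#' @param threshold good-access bound in minutes (default 120).
#' @return Named numeric vector of poor-access proportions per unit.
#' @export
poorAccessByUnit <- function(surface, births, units, threshold = 120) {
  stopIfGridMismatch(surface, units, "surface and admin units")
  lk <- birthCellLookup(births, surface@grid)
  ok <- !is.na(lk$cell)
  cell <- lk$cell[ok]; w <- lk$births[ok]
  minutes <- surface@values[cell]
  poor <- is.na(minutes) | minutes > threshold
  unit <- units@values[cell]
  nm <- units@unitNames
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  for (i in seq_along(nm)) {
    sel <- unit == i
    tot <- sum(w[sel])
    if (tot > 0) out[i] <- sum(w[sel & poor]) / tot
  }
  out
}

#' Demographic parameters for total-births estimation
#'
#' @param womenPop total population of women of reproductive age (15-49).
#' @param growthCoeff annual population growth coefficient (projects the
#'   population one year forward).
#' @param fertilityRate age-specific fertility rate, births per woman per
#'   year.
#' @return Validated list of the three parameters.
#' @export
demographicParams <- function(womenPop, growthCoeff, fertilityRate) {
  if (any(c(womenPop, growthCoeff, fertilityRate) <= 0))
    stop("all demographic parameters must be positive")
  list(womenPop = womenPop, growthCoeff = growthCoeff,
       fertilityRate = fertilityRate)
}

#' Estimated total births in a catchment
#'
#' The product of the reproductive-age female population, the annual growth
#' coefficient, the fertility rate, and the proportion of births occurring
#' in the catchment.
#'
#' @param proportion proportion of births in the catchment (0..1).
#' @param demo parameters from \code{\link{demographicParams}}.
#' @return Expected birth count.
#' @export
estimateTotalBirths <- function(proportion, demo) {
  if (any(proportion < 0 | proportion > 1))
    stop("proportion must be in [0, 1]")
  demo$womenPop * demo$growthCoeff * demo$fertilityRate * proportion
}

# births covered (centre within threshold minutes) by a minutes vector
# indexed like the analysis matrix
coveredBirths <- function(minutesVec, lk, threshold) {
  ok <- !is.na(lk$cell)
  m <- minutesVec[lk$cell[ok]]
  sum(lk$births[ok][!is.na(m) & m <= threshold])
}

#' Rank facility-upgrade candidates by newly covered births
#'
#' Implements the upgrade-prioritization rule: candidates located in areas
#' of suboptimal travel time but high birth density come first. Each
#' candidate's gain is the birth count inside the 2-hour catchment of
#' existing facilities plus the candidate, minus the births covered by the
#' existing facilities alone. In greedy mode the best candidate is picked,
#' the baseline updated, and gains recomputed, \code{k} times (coverage is
#' a union count, so greedy gains are non-increasing).
#'
#' @param candidates,existing facility data.frames (id, x, y, ...);
#'   disjoint sets.
#' @param combined combined \linkS4class{ClassRaster}.
#' @param dem \linkS4class{Dem}.
#' @param table \linkS4class{SpeedTable}.
#' @param births \linkS4class{BirthRaster}.
#' @param k number of greedy picks (ignored unless \code{greedy}).
#' @param greedy recompute gains after each pick.
#' @param threshold good-access bound in minutes (default 120).
#' @param config,params engine options.
#' @return data.frame (\code{id}, \code{gain_births}) sorted by decreasing
#'   gain, ties broken by id; in greedy mode, rows in pick order.
#' @export
rankUpgradeCandidates <- function(candidates, existing, combined, dem, table,
                                  births, k = 1L, greedy = FALSE,
                                  threshold = 120,
                                  config = EngineConfig(),
                                  params = ToblerParams()) {
  if (nrow(candidates) == 0L)
    return(data.frame(id = character(0), gain_births = numeric(0)))
  if (any(candidates$id %in% existing$id))
    stop("candidates must be disjoint from existing facilities")
  lk <- birthCellLookup(births, combined@grid)
  baseSrc <- snapFacilities(existing, combined)
  base <- accumulateTravelTime(combined, dem, table, baseSrc,
                               config = config, params = params)@values
  candSurf <- lapply(seq_len(nrow(candidates)), function(i) {
    src <- snapFacilities(candidates[i, , drop = FALSE], combined)
    accumulateTravelTime(combined, dem, table, src,
                         config = config, params = params)@values
  })
  names(candSurf) <- candidates$id

  gains <- function(baseVec, pool) {
    baseCov <- coveredBirths(baseVec, lk, threshold)
    vapply(pool, function(id) {
      coveredBirths(pmin(baseVec, candSurf[[id]], na.rm = TRUE), lk,
                    threshold) - baseCov
    }, numeric(1))
  }

  if (!greedy) {
    g <- gains(base, candidates$id)
    ord <- order(-g, candidates$id)
    return(data.frame(id = candidates$id[ord], gain_births = unname(g[ord]),
                      stringsAsFactors = FALSE))
  }
  pool <- candidates$id
  picks <- character(0); pickGain <- numeric(0)
  cur <- base
  for (step in seq_len(min(k, length(pool)))) {
    g <- gains(cur, pool)
    best <- pool[order(-g, pool)][1]
    picks <- c(picks, best)
    pickGain <- c(pickGain, g[[best]])
    cur <- pmin(cur, candSurf[[best]], na.rm = TRUE)
    pool <- setdiff(pool, best)
  }
  data.frame(id = picks, gain_births = pickGain, stringsAsFactors = FALSE)
}
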