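#' Attribute a disturbance year to the predating or postdating period
#'
#' Disturbances occurring before or during a dataset's mapping year are
#' attributed to the predating period (natural causes by assumption: had the
#' stand been disturbed anthropogenically it would not have been mapped as
#' primary forest); later disturbances are postdating and may be natural or
#' anthropogenic.
#'
#' @param disturbance_year,mapping_year Years within the disturbance window.
#' @param year_min,year_max Window bounds.
#' @return `"PRE"` iff `disturbance_year <= mapping_year`, else `"POST"`
#'   (vectorized over `disturbance_year`).
#' @export
attribute_period <- function(disturbance_year, mapping_year,
                             year_min = 1986L, year_max = 2020L) {
  if (any(disturbance_year < year_min | disturbance_year > year_max) ||
      any(mapping_year < year_min | mapping_year > year_max))
    stop("attribution error: year outside the disturbance window", call. = FALSE)
  ifelse(disturbance_year <= mapping_year, "PRE", "POST")
}

#' Period window lengths
#'
#' The predating window runs from `year_min` through the mapping year
#' inclusive; the postdating window from the next year through `year_max`.
#' A mapping year equal to `year_max` leaves a zero-length postdating window
#' (rates are then undefined, reported as NA).
#'
#' @param mapping_year Dataset mapping year (NA for the FULL window).
#' @param year_min,year_max Window bounds.
#' @return Named list with `PRE`, `POST`, `FULL` window lengths in years.
#' @export
period_lengths <- function(mapping_year, year_min = 1986L, year_max = 2020L) {
  full <- year_max - year_min + 1L
  if (is.na(mapping_year)) return(list(PRE = NA_integer_, POST = NA_integer_,
                                       FULL = full))
  list(PRE = mapping_year - year_min + 1L,
       POST = year_max - mapping_year,
       FULL = full)
}

#' Forest area of a polygon under the filtered forest mask
#'
#' @param cells Integer vector of the polygon's linear cell indices.
#' @param forest_mask Logical matrix, already MMU-filtered.
#' @param grid The [pf_grid()].
#' @return Hectares: forest cell count times the cell area.
#' @export
polygon_forest_area <- function(cells, forest_mask, grid) {
  sum(forest_mask[cells]) * cell_area_ha(grid)
}

#' Disturbed area in a polygon split by period
#'
#' Each disturbed cell inside the polygon (and inside the filtered forest
#' mask) contributes one cell area to exactly one period, so PRE + POST equals
#' the polygon's total disturbed area.
#'
#' @param cells Polygon cell indices, already intersected with the filtered
#'   forest mask by the caller (or not; the mask is applied here).
#' @param layers A [disturbance_layers()].
#' @param forest_mask MMU-filtered forest mask.
#' @param mapping_year Mapping year (NA for POTENTIAL datasets: all area goes
#'   to FULL).
#' @return Named numeric: `PRE`, `POST`, `FULL` hectares.
#' @export
disturbed_area_by_period <- function(cells, layers, forest_mask, mapping_year) {
  aha <- cell_area_ha(layers$grid)
  yr <- layers$year[cells]
  ok <- yr != 0L & forest_mask[cells]
  yr <- yr[ok]
  full <- length(yr) * aha
  if (is.na(mapping_year)) return(c(PRE = NA_real_, POST = NA_real_, FULL = full))
  pre <- sum(yr <= mapping_year) * aha
  c(PRE = pre, POST = full - pre, FULL = full)
}

#' Proportion of forest area disturbed
#'
#' @param disturbed_ha,total_forest_ha Hectares.
#' @return `100 * disturbed_ha / total_forest_ha`, or `NA` when the forest
#'   area is zero (undefined proportion).
#' @export
proportion_disturbed <- function(disturbed_ha, total_forest_ha) {
  ifelse(total_forest_ha > 0, 100 * disturbed_ha / total_forest_ha, NA_real_)
}

#' Mean annual rate of area disturbed
#'
#' Disturbed area per year as a percentage of forest area; this normalizes
#' the imbalance between the long predating and short postdating windows.
#'
#' @param disturbed_ha,forest_ha Hectares.
#' @param n_years Window length in years (>= 1).
#' @return Percent per year: `100 * disturbed_ha / (forest_ha * n_years)`.
#' @export
annual_rate <- function(disturbed_ha, forest_ha, n_years) {
  if (any(!is.na(n_years) & n_years < 1))
    stop("parameter error: n_years must be >= 1", call. = FALSE)
  ifelse(forest_ha > 0 & !is.na(n_years),
         100 * disturbed_ha / (forest_ha * n_years), NA_real_)
}

#' Change in the mean annual disturbance rate
#'
#' @param rate_pre,rate_post Percent per year.
#' @return `rate_post - rate_pre`.
#' @export
rate_change <- function(rate_pre, rate_post) rate_post - rate_pre

#' Area-weighted mean mapping year
#'
#' @param mapping_years Mapping year per dataset.
#' @param areas_ha Polygon area per dataset (weights).
#' @return `sum(area * year) / sum(area)`.
#' @export
weighted_mean_mapping_year <- function(mapping_years, areas_ha) {
  ok <- !is.na(mapping_years) & !is.na(areas_ha)
  if (!any(ok) || sum(areas_ha[ok]) <= 0)
    stop("no documented dataset with positive area", call. = FALSE)
  sum(areas_ha[ok] * mapping_years[ok]) / sum(areas_ha[ok])
}

# Aggregate polygon-level period areas into one indicator row per
# stratum x status x period. `poly` is the per-polygon table built by
# assess_disturbance(); rates are recomputed from pooled areas, with the
# denominator summed as forest_ha * n_years over member polygons (this
# reduces to annual_rate() when all polygons share one mapping year).
# Sums are carried as integer cell counts and converted to hectares once,
# so additivity across strata is exact, not merely within rounding.
.aggregate_records <- function(poly, strata, aha) {
  out <- list()
  for (si in seq_len(nrow(strata))) {
    stype <- strata$stratum_type[si]; scode <- strata$stratum[si]
    member <- switch(stype,
      country   = poly$country == scode,
      bioregion = poly$bioregion == scode,
      eu        = poly$in_eu,
      europe    = rep(TRUE, nrow(poly)))
    for (status in unique(poly$status[member])) {
      rows <- poly[member & poly$status == status, , drop = FALSE]
      periods <- if (status == "DOCUMENTED") c("PRE", "POST") else "FULL"
      for (per in periods) {
        dist_cells <- sum(rows[[paste0("cells_", tolower(per))]])
        dist_ha <- dist_cells * aha
        ny <- rows[[paste0("nyears_", tolower(per))]]
        denom <- sum(as.numeric(rows$fcells) * ny) * aha
        forest_cells <- sum(rows$fcells)
        forest_ha <- forest_cells * aha
        out[[length(out) + 1L]] <- data.frame(
          stratum_type = stype, stratum = scode, status = status, period = per,
          n_polygons = nrow(rows),
          forest_cells = forest_cells, forest_area_ha = forest_ha,
          disturbed_cells = dist_cells, disturbed_area_ha = dist_ha,
          proportion_pct = proportion_disturbed(dist_ha, forest_ha),
          rate_pct_yr = if (!is.na(denom) && denom > 0)
            100 * dist_ha / denom else NA_real_)
      }
    }
  }
  do.call(rbind, out)
}
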