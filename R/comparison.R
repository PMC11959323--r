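#' Combined per-country extent of documented and potential primary forest
#'
#' Sums the forest area of the two layers per country (overlaps between the
#' layers are already removed at assessment time: potential polygons are
#' clipped under documented ones). The combination exists only for comparison
#' against externally reported areas; all indicator computations keep the two
#' statuses separate.
#'
#' @param indicators Indicator table from a `pf_assessment` (country rows are
#'   used), or any data.frame with `stratum_type`, `stratum`, `status`,
#'   `period`, `forest_area_ha`.
#' @return data.frame: `country`, `documented_ha`, `potential_ha`,
#'   `combined_ha`, plus a final `EUROPE` row holding the column sums.
#' @export
combined_area <- function(indicators) {
  cc <- indicators[indicators$stratum_type == "country", , drop = FALSE]
  # one row per country x status suffices (forest area is period-invariant)
  cc <- cc[!duplicated(cc[, c("stratum", "status")]), , drop = FALSE]
  countries <- sort(unique(cc$stratum))
  pick <- function(ctry, status) {
    v <- cc$forest_area_ha[cc$stratum == ctry & cc$status == status]
    if (length(v)) v[1] else 0
  }
  out <- data.frame(
    country = countries,
    documented_ha = vapply(countries, pick, numeric(1), status = "DOCUMENTED"),
    potential_ha = vapply(countries, pick, numeric(1), status = "POTENTIAL"))
  out$combined_ha <- out$documented_ha + out$potential_ha
  rbind(out, data.frame(country = "EUROPE",
                        documented_ha = sum(out$documented_ha),
                        potential_ha = sum(out$potential_ha),
                        combined_ha = sum(out$combined_ha)))
}

#' Discrepancy between combined mapped and reported primary-forest areas
#'
#' @param combined Output of [combined_area()] (or a data.frame with
#'   `country` and `combined_ha`).
#' @param reported data.frame with `country`, `reported_area_ha` and
#'   optionally `source`.
#' @return data.frame per matched country: combined and reported hectares,
#'   `difference_ha = combined - reported` and `ratio_pct = 100 * combined /
#'   reported` (NA when reported is zero, with `flagged = TRUE`). Countries
#'   present on only one side are listed with NA on the other and flagged.
#' @export
discrepancy <- function(combined, reported) {
  if (any(reported$reported_area_ha < 0, na.rm = TRUE))
    stop("reported areas must be >= 0", call. = FALSE)
  if (anyDuplicated(reported$country))
    stop("country codes must be unique in the reported table", call. = FALSE)
  m <- merge(combined[, c("country", "combined_ha")],
             reported[, c("country", "reported_area_ha")],
             by = "country", all = TRUE)
  m$difference_ha <- m$combined_ha - m$reported_area_ha
  m$ratio_pct <- ifelse(!is.na(m$reported_area_ha) & m$reported_area_ha > 0,
                        100 * m$combined_ha / m$reported_area_ha, NA_real_)
  m$flagged <- is.na(m$combined_ha) | is.na(m$reported_area_ha) |
    m$reported_area_ha == 0
  m[order(m$country), ]
}
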