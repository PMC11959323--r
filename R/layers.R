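#' Co-registered disturbance, severity and forest layers
#'
#' Bundles the three rasters of the disturbance product on a common grid:
#' per-cell disturbance year (integer, 0 = undisturbed), per-cell disturbance
#' severity (fraction of canopy lost, 0-1, `NA` where not available) and the
#' binary forest mask. The disturbance window defaults to 1986-2020 and the
#' severity product ends in 2016, mirroring the Landsat-derived European maps.
#'
#' @param grid A [pf_grid()].
#' @param year Integer matrix `nrows x ncols`; 0 for undisturbed, otherwise a
#'   year in `[year_min, year_max]`.
#' @param severity Numeric matrix in `[0, 1]` or `NA` (no data).
#' @param forest Logical (or 0/1) matrix, `TRUE` = forest.
#' @param year_min,year_max Bounds of the disturbance window.
#' @param severity_year_max Last year covered by the severity product.
#' @return An object of class `disturbance_layers`.
#' @export
disturbance_layers <- function(grid, year, severity, forest,
                               year_min = 1986L, year_max = 2020L,
                               severity_year_max = 2016L) {
  stopifnot(inherits(grid, "pf_grid"))
  dims <- c(grid$nrows, grid$ncols)
  for (nm in c("year", "severity", "forest")) {
    m <- get(nm)
    if (!is.matrix(m) || !identical(dim(m), as.integer(dims)))
      stop(sprintf("co-registration error: '%s' layer is not %d x %d",
                   nm, dims[1], dims[2]), call. = FALSE)
  }
  if (year_min > year_max)
    stop("year_min must not exceed year_max", call. = FALSE)
  year <- matrix(as.integer(year), dims[1], dims[2])
  bad_year <- sum(!is.na(year) & year != 0L &
                    (year < year_min | year > year_max), na.rm = TRUE)
  if (bad_year > 0L)
    stop(sprintf("validation error: %d year value(s) outside [%d, %d] (0 = undisturbed)",
                 bad_year, year_min, year_max), call. = FALSE)
  if (anyNA(year)) stop("validation error: year layer contains NA; use 0 for undisturbed",
                        call. = FALSE)
  severity <- matrix(as.numeric(severity), dims[1], dims[2])
  bad_sev <- sum(!is.na(severity) & (severity < 0 | severity > 1))
  if (bad_sev > 0L)
    stop(sprintf("validation error: %d severity value(s) outside [0, 1]", bad_sev),
         call. = FALSE)
  forest <- matrix(as.logical(forest), dims[1], dims[2])
  if (anyNA(forest)) stop("validation error: forest mask contains NA", call. = FALSE)
  structure(
    list(grid = grid, year = year, severity = severity, forest = forest,
         year_min = as.integer(year_min), year_max = as.integer(year_max),
         severity_year_max = as.integer(severity_year_max)),
    class = "disturbance_layers")
}

#' @export
print.disturbance_layers <- function(x, ...) {
  nd <- sum(x$year != 0L)
  cat(sprintf("<disturbance_layers> %d x %d @ %g m | window %d-%d (severity to %d)\n",
              x$grid$nrows, x$grid$ncols, x$grid$cell_size,
              x$year_min, x$year_max, x$severity_year_max))
  cat(sprintf("  forest cells: %d (%.1f%%) | disturbed cells: %d (%.2f%% of forest)\n",
              sum(x$forest), 100 * mean(x$forest), nd,
              if (sum(x$forest) > 0) 100 * nd / sum(x$forest) else 0))
  invisible(x)
}
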