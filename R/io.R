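#' @title Raster and vector input/output
#' @description Rasters are exchanged as single-band ESRI ASCII grids (.asc), a
#'   plain-text format carrying ncols/nrows/cell size/lower-left corner/NODATA
#'   in its header. Polygon layers are exchanged as GeoJSON FeatureCollections
#'   with the attribute columns `polygon_id`, `dataset_id`, `country`,
#'   `bioregion`, `in_eu`; the dataset table (dataset_id, status, mapping_year)
#'   is a CSV.
#' @name pfdisturb-io
NULL

# sentinels used on disk; in memory year 0 = undisturbed, severity NA = nodata
.YEAR_UNDISTURBED <- 0L
.SEV_NODATA <- -1

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m Numeric matrix (row 1 = northernmost row).
#' @param path Output file.
#' @param grid A [pf_grid()] supplying cell size and lower-left corner.
#' @param nodata NODATA_value written in the header; `NA` cells map to it.
#' @param digits Significant digits for non-integer values.
#' @export
write_asc <- function(m, path, grid, nodata = -9999, digits = 7) {
  stopifnot(is.matrix(m), inherits(grid, "pf_grid"),
            nrow(m) == grid$nrows, ncol(m) == grid$ncols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  m[is.na(m)] <- nodata
  rows <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Input file.
#' @return List with `matrix` (NODATA as `NA`) and the `pf_grid` implied by
#'   the header.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed .asc header in ", path, call. = FALSE)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("malformed .asc body in %s: %d values, expected %d",
                 path, length(vals), nr * nc), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid <- pf_grid(nr, nc, hdr$cellsize,
                  origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0))
  list(matrix = m, grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the three co-registered layers from ESRI ASCII grids
#'
#' Severity NODATA may be encoded either via the header NODATA_value or the
#' negative in-band sentinel -1. Grids must agree in shape, cell size and
#' corner coordinates.
#'
#' @param year_path,severity_path,forest_path Paths to the three .asc files.
#' @param year_min,year_max,severity_year_max Window, as in
#'   [disturbance_layers()].
#' @return A [disturbance_layers()] object.
#' @export
read_layers <- function(year_path, severity_path, forest_path,
                        year_min = 1986L, year_max = 2020L,
                        severity_year_max = 2016L) {
  y <- read_asc(year_path); s <- read_asc(severity_path); f <- read_asc(forest_path)
  for (o in list(s, f)) {
    same <- o$grid$nrows == y$grid$nrows && o$grid$ncols == y$grid$ncols &&
      isTRUE(all.equal(o$grid$cell_size, y$grid$cell_size)) &&
      isTRUE(all.equal(o$grid$origin, y$grid$origin))
    if (!same) stop("co-registration error: layers differ in shape or transform",
                    call. = FALSE)
  }
  ym <- y$matrix; ym[is.na(ym)] <- .YEAR_UNDISTURBED
  sm <- s$matrix; sm[!is.na(sm) & sm < 0] <- NA
  fm <- f$matrix; fm[is.na(fm)] <- 0
  disturbance_layers(y$grid, ym, sm, fm != 0,
                     year_min = year_min, year_max = year_max,
                     severity_year_max = severity_year_max)
}

#' Write the three layers as ESRI ASCII grids
#'
#' Integer layers round-trip bit-exactly; severity within float text precision.
#'
#' @param layers A [disturbance_layers()].
#' @param year_path,severity_path,forest_path Output paths.
#' @export
write_layers <- function(layers, year_path, severity_path, forest_path) {
  stopifnot(inherits(layers, "disturbance_layers"))
  g <- layers$grid
  write_asc(layers$year, year_path, g, nodata = -9999)
  sev <- layers$severity
  write_asc(sev, severity_path, g, nodata = .SEV_NODATA, digits = 9)
  write_asc(layers$forest * 1L, forest_path, g, nodata = -9999)
  invisible(c(year_path, severity_path, forest_path))
}

#' A polygon feature of a primary-forest layer
#'
#' @param polygon_id,dataset_id Identifiers.
#' @param country,bioregion Stratum codes (the Alpine region is expected to be
#'   pre-split into its Scandinavian and southern subregions upstream).
#' @param in_eu Logical EU membership of the polygon's country.
#' @param rings List of n x 2 coordinate matrices (outer ring first; further
#'   rings are holes, even-odd rule).
#' @return Object of class `pf_polygon`.
#' @export
pf_polygon <- function(polygon_id, dataset_id, country, bioregion, in_eu, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(length(rings) >= 1L)
  for (r in rings) stopifnot(is.matrix(r), ncol(r) == 2L, nrow(r) >= 3L)
  if (anyNA(c(country, bioregion, in_eu)) || !nzchar(country) || !nzchar(bioregion))
    stop("polygon stratum attributes must be non-null", call. = FALSE)
  structure(list(polygon_id = as.character(polygon_id),
                 dataset_id = as.character(dataset_id),
                 country = as.character(country),
                 bioregion = as.character(bioregion),
                 in_eu = as.logical(in_eu), rings = rings),
            class = "pf_polygon")
}

#' Read a polygon layer from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features with
#' properties `polygon_id`, `dataset_id`, `country`, `bioregion`, `in_eu`.
#'
#' @param path GeoJSON file.
#' @return List of [pf_polygon()] objects.
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  lapply(gj$features, function(f) {
    p <- f$properties
    need <- c("polygon_id", "dataset_id", "country", "bioregion", "in_eu")
    miss <- setdiff(need, names(p))
    if (length(miss)) stop("polygon feature missing properties: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    g <- f$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(g$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", g$type, call. = FALSE))
    pf_polygon(p$polygon_id, p$dataset_id, p$country, p$bioregion, p$in_eu, rings)
  })
}

#' Write a polygon layer to GeoJSON
#'
#' @param polygons List of [pf_polygon()].
#' @param path Output file.
#' @export
write_polygons <- function(polygons, path) {
  feats <- lapply(polygons, function(pp) {
    coords <- lapply(pp$rings, function(r) {
      if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
    })
    list(type = "Feature",
         properties = list(polygon_id = pp$polygon_id, dataset_id = pp$dataset_id,
                           country = pp$country, bioregion = pp$bioregion,
                           in_eu = pp$in_eu),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / validate the dataset table
#'
#' @param path CSV with columns dataset_id, status (DOCUMENTED/POTENTIAL),
#'   mapping_year (empty for POTENTIAL).
#' @param year_min,year_max Window used to validate mapping years.
#' @return data.frame with character `dataset_id`, character `status`,
#'   integer `mapping_year` (NA for POTENTIAL).
#' @export
read_dataset_table <- function(path, year_min = 1986L, year_max = 2020L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset_table(d, year_min, year_max)
}

#' @rdname read_dataset_table
#' @param d A data.frame with the dataset-table columns.
#' @export
validate_dataset_table <- function(d, year_min = 1986L, year_max = 2020L) {
  need <- c("dataset_id", "status", "mapping_year")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dataset table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d$dataset_id <- as.character(d$dataset_id)
  d$status <- toupper(as.character(d$status))
  if (!all(d$status %in% c("DOCUMENTED", "POTENTIAL")))
    stop("dataset status must be DOCUMENTED or POTENTIAL", call. = FALSE)
  d$mapping_year <- suppressWarnings(as.integer(d$mapping_year))
  doc <- d$status == "DOCUMENTED"
  if (any(doc & is.na(d$mapping_year)))
    stop("configuration error: DOCUMENTED dataset without mapping_year",
         call. = FALSE)
  bad <- doc & (d$mapping_year < year_min | d$mapping_year > year_max)
  if (any(bad))
    stop(sprintf("configuration error: mapping_year outside [%d, %d] for: %s",
                 year_min, year_max,
                 paste(d$dataset_id[bad], collapse = ", ")), call. = FALSE)
  d$mapping_year[!doc] <- NA_integer_
  if (anyDuplicated(d$dataset_id))
    stop("dataset_id values must be unique", call. = FALSE)
  d
}
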