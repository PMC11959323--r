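#' Planar equal-area analysis grid
#'
#' Defines the common grid on which the disturbance-year, severity and forest
#' rasters live. The grid is planar with square cells; areas are computed as
#' cell counts times the cell area, so the coordinate reference is expected to
#' be an equal-area projection (the `crs_tag` is free text and only inspected
#' to warn when it looks geographic).
#'
#' Rows are numbered from the top (north) down, columns left to right,
#' 1-based as usual in R. `origin` is the (x, y) map coordinate of the grid's
#' lower-left corner, so the center of cell (row r, col c) is at
#' `x = origin[1] + (c - 0.5) * cell_size`,
#' `y = origin[2] + (nrows - r + 0.5) * cell_size`.
#'
#' @param nrows,ncols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in meters (> 0). Default 30, the grid
#'   size of the Landsat-derived European disturbance product.
#' @param origin Numeric length-2, map coordinates of the lower-left corner.
#' @param crs_tag Free-text CRS description; expected equal-area.
#' @return An object of class `pf_grid`.
#' @examples
#' g <- pf_grid(4, 4)
#' cell_area_ha(g)  # 0.09 ha at 30 m
#' @export
pf_grid <- function(nrows, ncols, cell_size = 30, origin = c(0, 0),
                    crs_tag = "local-equal-area") {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (is.na(nrows) || is.na(ncols) || nrows < 1L || ncols < 1L)
    stop("invalid grid: nrows and ncols must be >= 1", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      is.na(cell_size) || cell_size <= 0)
    stop("invalid grid: cell_size must be a positive number", call. = FALSE)
  if (!is.numeric(origin) || length(origin) != 2L || anyNA(origin))
    stop("invalid grid: origin must be numeric length 2", call. = FALSE)
  if (grepl("4326|longlat|WGS\\s*84|geographic", crs_tag, ignore.case = TRUE))
    warning("crs_tag looks geographic; areas assume an equal-area planar grid",
            call. = FALSE)
  structure(
    list(nrows = nrows, ncols = ncols, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_tag = as.character(crs_tag)),
    class = "pf_grid")
}

#' @export
print.pf_grid <- function(x, ...) {
  cat(sprintf("<pf_grid> %d x %d cells, %g m (%g ha/cell), origin (%g, %g), crs: %s\n",
              x$nrows, x$ncols, x$cell_size, cell_area_ha(x),
              x$origin[1], x$origin[2], x$crs_tag))
  invisible(x)
}

#' Area of one grid cell in hectares
#'
#' @param grid A [pf_grid()].
#' @return `cell_size^2 / 10000`.
#' @export
cell_area_ha <- function(grid) {
  stopifnot(inherits(grid, "pf_grid"))
  grid$cell_size^2 / 1e4
}

#' Map coordinates of cell centers
#'
#' @param grid A [pf_grid()].
#' @param rows,cols 1-based row/column indices (row 1 at the top).
#' @return A two-column matrix of (x, y) center coordinates.
#' @export
cell_centers <- function(grid, rows, cols) {
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
        y = grid$origin[2] + (grid$nrows - rows + 0.5) * grid$cell_size)
}

# Half-open crossing-number point-in-polygon test.
#
# A point is inside when a ray to +x crosses an odd number of edges, edges
# taken half-open in y ([ymin, ymax)). The practical effect is the lower-left
# rasterization rule: a point on a polygon's bottom or left boundary counts as
# inside, on the top or right boundary as outside, so tiling polygons
# partition cell centers exactly (area additivity holds with equality).
# `ring` is an n x 2 matrix; the ring need not repeat its first vertex.
.ring_crossings <- function(px, py, ring) {
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    spans <- (yi > py) != (yj > py)
    if (any(spans)) {
      xint <- xi + (py[spans] - yi) / (yj - yi) * (xj - xi)
      hit <- px[spans] < xint
      idx <- which(spans)[hit]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  inside
}

# Even-odd test across all rings (holes supported).
.points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) inside <- xor(inside, .ring_crossings(px, py, ring))
  inside
}

#' Rasterize a polygon to a set of grid cells
#'
#' A cell belongs to the result iff its center lies inside the polygon under
#' the even-odd rule with half-open edges (bottom/left boundary inside,
#' top/right outside). This makes rasterization deterministic and exactly
#' additive over tiling polygons.
#'
#' @param polygon A `pf_polygon` (see [pf_polygon()]) or a bare list with a
#'   `rings` element (list of n x 2 coordinate matrices in grid map units).
#' @param grid A [pf_grid()].
#' @return Sorted integer vector of linear cell indices (column-major, as used
#'   by R matrices over the grid). A polygon wholly outside the grid yields an
#'   empty vector.
#' @export
rasterize_polygon <- function(polygon, grid) {
  stopifnot(inherits(grid, "pf_grid"))
  rings <- if (!is.null(polygon$rings)) polygon$rings else polygon
  if (!is.list(rings) || length(rings) == 0L)
    stop("geometry error: polygon has no rings", call. = FALSE)
  for (r in rings) {
    if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L || anyNA(r))
      stop("geometry error: each ring must be an n x 2 numeric matrix, n >= 3, no NA",
           call. = FALSE)
  }
  cs <- grid$cell_size
  xs <- range(vapply(rings, function(r) range(r[, 1L]), numeric(2)))
  ys <- range(vapply(rings, function(r) range(r[, 2L]), numeric(2)))
  # candidate cells restricted to the polygon bounding box
  cmin <- max(1L, floor((xs[1] - grid$origin[1]) / cs - 0.5) + 1L)
  cmax <- min(grid$ncols, ceiling((xs[2] - grid$origin[1]) / cs + 0.5))
  rmin <- max(1L, floor((grid$origin[2] + grid$nrows * cs - ys[2]) / cs - 0.5) + 1L)
  rmax <- min(grid$nrows, ceiling((grid$origin[2] + grid$nrows * cs - ys[1]) / cs + 0.5))
  if (cmin > cmax || rmin > rmax) return(integer(0))
  rows <- rep(rmin:rmax, times = cmax - cmin + 1L)
  cols <- rep(cmin:cmax, each = rmax - rmin + 1L)
  ctr <- cell_centers(grid, rows, cols)
  keep <- .points_in_rings(ctr[, 1L], ctr[, 2L], rings)
  sort(rows[keep] + (cols[keep] - 1L) * grid$nrows)
}
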