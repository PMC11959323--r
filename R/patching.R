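#' Delineate patches by rook contiguity
#'
#' Disturbance patches are maximal 4-connected (rook: shared edges only)
#' components of cells sharing the same disturbance year; cells disturbed in
#' different years never share a patch. Forest patches are 4-connected
#' components of the forest mask. Every disturbed (resp. forest) cell belongs
#' to exactly one patch.
#'
#' Patch mean severity is the arithmetic mean of the severity of all cells on
#' the patch, defined only for disturbance patches with year <=
#' `severity_year_max`; patches containing any severity NODATA cell get
#' `mean_severity = NA` and `severity_valid = FALSE` so they can be excluded
#' (and counted) by severity summaries.
#'
#' @param layers A [disturbance_layers()].
#' @param scope `"disturbance"` or `"forest"`.
#' @return A data.frame of class `pf_patches` with columns `patch_id`, `year`
#'   (NA for forest patches), `n_cells`, `area_ha`, `mean_severity`,
#'   `severity_valid`, and an attribute `cells`: a list of integer vectors of
#'   linear cell indices (column-major).
#' @export
label_patches <- function(layers, scope = c("disturbance", "forest")) {
  stopifnot(inherits(layers, "disturbance_layers"))
  scope <- match.arg(scope)
  nr <- layers$grid$nrows; nc <- layers$grid$ncols
  val <- if (scope == "disturbance") layers$year else (layers$forest * 1L)
  if (scope == "forest") val[!layers$forest] <- 0L
  cells <- which(val != 0L)
  if (length(cells) == 0L) return(.empty_patches(layers))
  # edges between rook neighbors holding the same (nonzero) value
  idmap <- integer(nr * nc)
  idmap[cells] <- seq_along(cells)
  edges <- NULL
  if (nr > 1L) {
    a <- val[-nr, , drop = FALSE]; b <- val[-1L, , drop = FALSE]
    hit <- which(a != 0L & a == b)
    if (length(hit)) {
      rr <- (hit - 1L) %% (nr - 1L) + 1L
      cc <- (hit - 1L) %/% (nr - 1L) + 1L
      i1 <- rr + (cc - 1L) * nr
      edges <- rbind(edges, cbind(idmap[i1], idmap[i1 + 1L]))
    }
  }
  if (nc > 1L) {
    a <- val[, -nc, drop = FALSE]; b <- val[, -1L, drop = FALSE]
    hit <- which(a != 0L & a == b)
    if (length(hit)) {
      i1 <- hit  # linear index in the nr x (nc-1) submatrix == linear index in val
      edges <- rbind(edges, cbind(idmap[i1], idmap[i1 + nr]))
    }
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  cell_lists <- split(cells, comp)
  # deterministic patch order: by smallest member cell index
  ord <- order(vapply(cell_lists, min, numeric(1)))
  cell_lists <- unname(cell_lists[ord])
  n_cells <- lengths(cell_lists)
  first <- vapply(cell_lists, `[[`, integer(1), 1L)
  yr <- if (scope == "disturbance") layers$year[first] else rep(NA_integer_, length(first))
  aha <- cell_area_ha(layers$grid)
  mean_sev <- rep(NA_real_, length(cell_lists))
  sev_ok <- rep(NA, length(cell_lists))
  if (scope == "disturbance") {
    eligible <- yr <= layers$severity_year_max
    for (i in which(eligible)) {
      sv <- layers$severity[cell_lists[[i]]]
      if (anyNA(sv)) { sev_ok[i] <- FALSE } else {
        sev_ok[i] <- TRUE; mean_sev[i] <- mean(sv)
      }
    }
    sev_ok[!eligible] <- FALSE
  }
  out <- data.frame(patch_id = seq_along(cell_lists), year = yr,
                    n_cells = as.integer(n_cells),
                    area_ha = n_cells * aha,
                    mean_severity = mean_sev,
                    severity_valid = sev_ok)
  attr(out, "cells") <- cell_lists
  attr(out, "scope") <- scope
  class(out) <- c("pf_patches", "data.frame")
  out
}

.empty_patches <- function(layers) {
  out <- data.frame(patch_id = integer(0), year = integer(0),
                    n_cells = integer(0), area_ha = numeric(0),
                    mean_severity = numeric(0), severity_valid = logical(0))
  attr(out, "cells") <- list()
  class(out) <- c("pf_patches", "data.frame")
  out
}

#' Enforce the minimum mapping unit
#'
#' Removes patches smaller than `min_cells` grid cells (default 2 cells,
#' i.e. 0.18 ha on the 30-m grid). The bound is inclusive: a patch of exactly
#' `min_cells` cells is the smallest retained unit. Input order is preserved
#' and the operation is idempotent.
#'
#' @param patches A `pf_patches` from [label_patches()].
#' @param min_cells Minimum retained patch size in cells (>= 1).
#' @return Filtered `pf_patches`.
#' @export
apply_mmu <- function(patches, min_cells = 2L) {
  stopifnot(inherits(patches, "pf_patches"))
  min_cells <- as.integer(min_cells)
  if (is.na(min_cells) || min_cells < 1L)
    stop("parameter error: min_cells must be >= 1", call. = FALSE)
  keep <- patches$n_cells >= min_cells
  out <- patches[keep, , drop = FALSE]
  attr(out, "cells") <- attr(patches, "cells")[keep]
  attr(out, "scope") <- attr(patches, "scope")
  class(out) <- c("pf_patches", "data.frame")
  rownames(out) <- NULL
  out
}

#' Remove sub-MMU forest patches from the forest mask
#'
#' @param layers A [disturbance_layers()].
#' @param min_cells Minimum forest-component size in cells.
#' @return Logical matrix: the forest mask with every component smaller than
#'   `min_cells` removed (a subset of the input mask).
#' @export
filtered_forest_mask <- function(layers, min_cells = 2L) {
  p <- apply_mmu(label_patches(layers, "forest"), min_cells)
  mask <- matrix(FALSE, layers$grid$nrows, layers$grid$ncols)
  cl <- attr(p, "cells")
  if (length(cl)) mask[unlist(cl, use.names = FALSE)] <- TRUE
  mask
}

#' Patch table export
#'
#' @param patches A `pf_patches`.
#' @param grid The [pf_grid()] the patches live on (for centroids).
#' @return data.frame with patch_id, year, n_cells, area_ha, mean_severity and
#'   centroid row/col (1-based, fractional).
#' @export
patch_table <- function(patches, grid) {
  cl <- attr(patches, "cells")
  nr <- grid$nrows
  cent <- t(vapply(cl, function(cells) {
    r <- (cells - 1L) %% nr + 1L; c <- (cells - 1L) %/% nr + 1L
    c(mean(r), mean(c))
  }, numeric(2)))
  if (length(cl) == 0L) cent <- matrix(numeric(0), 0, 2)
  cbind(as.data.frame(patches)[, c("patch_id", "year", "n_cells", "area_ha",
                                   "mean_severity")],
        centroid_row = cent[, 1L], centroid_col = cent[, 2L])
}
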