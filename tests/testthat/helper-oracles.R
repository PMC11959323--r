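# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: the flood fill grows components
# one 4-neighbor at a time from an explicit queue.

# Label same-value rook-connected components of a matrix (0 = background).
# Returns a list of sorted linear-index vectors, ordered by smallest member.
flood_fill_components <- function(val) {
  nr <- nrow(val); nc <- ncol(val)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (cc in seq_len(nc)) for (r in seq_len(nr)) {
    if (val[r, cc] == 0 || seen[r, cc]) next
    v <- val[r, cc]
    queue <- list(c(r, cc))
    seen[r, cc] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- c(members, p[1] + (p[2] - 1L) * nr)
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1] >= 1L && q[1] <= nr && q[2] >= 1L && q[2] <= nc &&
            !seen[q[1], q[2]] && val[q[1], q[2]] == v) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Canonical form of a patch partition for comparison: sorted list of sorted
# cell-index vectors.
canonical_partition <- function(cell_lists) {
  cl <- lapply(cell_lists, sort)
  cl[order(vapply(cl, min, numeric(1)))]
}

# Small layer-set builder with permissive defaults.
make_layers <- function(year, severity = NULL, forest = NULL, cell_size = 30,
                        year_min = 1986L, year_max = 2020L,
                        severity_year_max = 2016L) {
  year <- as.matrix(year)
  if (is.null(severity)) {
    severity <- matrix(NA_real_, nrow(year), ncol(year))
    severity[year != 0 & year <= severity_year_max] <- 0.5
  }
  if (is.null(forest)) forest <- matrix(TRUE, nrow(year), ncol(year))
  disturbance_layers(pf_grid(nrow(year), ncol(year), cell_size),
                     year, severity, forest,
                     year_min = year_min, year_max = year_max,
                     severity_year_max = severity_year_max)
}

# Axis-aligned rectangle ring in map units.
rect_ring <- function(x0, y0, x1, y1)
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

# A deterministic mid-sized fixture bundle shared by several files.
fixture_sim <- function(seed = 2024L, nrows = 48L, ncols = 48L,
                        hazard_pre = 0.004, hazard_post = 0.008, ...) {
  simulate_landscape(landscape_config(
    nrows = nrows, ncols = ncols, seed = seed,
    hazard_pre = hazard_pre, hazard_post = hazard_post, ...))
}
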