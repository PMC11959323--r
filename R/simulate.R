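#' Configuration for the synthetic landscape generator
#'
#' The generator emulates the statistical structure the assessment assumes:
#' an annual per-cell disturbance hazard that can change after a
#' dataset-specific mapping year, rook-connected patches with a geometric
#' size distribution, Beta-distributed patch severity with cell-level jitter,
#' a Bernoulli forest mask, and rectangular polygon datasets stratified by
#' country and biogeographical region.
#'
#' `hazard_pre`/`hazard_post` are per-cell, per-year probabilities of
#' disturbance, so the true expected mean annual rate of area disturbed is
#' `100 * hazard` percent per year. Patches are seeded at probability
#' `hazard / mean_patch_cells` and grown to a target size of
#' `2 + Geometric` cells with mean `mean_patch_cells`; the minimum of 2 cells
#' equals the default minimum mapping unit, so the generator's truth remains
#' observable after MMU filtering. Cells are disturbed at most once
#' (first year wins), mirroring the single-year-per-cell disturbance product.
#'
#' @param nrows,ncols,cell_size Grid geometry.
#' @param year_min,year_max,severity_year_max Disturbance window (defaults
#'   1986-2020, severity to 2016).
#' @param forest_cover Bernoulli forest-mask cover fraction.
#' @param n_datasets Number of polygon datasets.
#' @param polygons_per_dataset Rectangular polygons per dataset.
#' @param mapping_years Mapping year per dataset (recycled); defaults to
#'   2013, 2015, 2017 - area-weighted mean about 2015, the weighted mean
#'   mapping year of the European inventory.
#' @param statuses Dataset status vector (recycled), DOCUMENTED/POTENTIAL.
#' @param hazard_pre,hazard_post Per-cell annual disturbance probability at or
#'   before / after the dataset mapping year. Defaults 0.0008 and 0.0015,
#'   echoing continental rates of 0.08 and 0.15 %/yr.
#' @param anthro_hazard Additional labeled "anthropogenic" hazard stream
#'   (active before the mapping year), used by the selection-bias mode.
#' @param selection_bias If `TRUE`, candidate DOCUMENTED polygons containing
#'   any pre-mapping anthropogenic disturbance are excluded from the polygon
#'   layer, reproducing the selection bias of primary-forest maps.
#' @param mean_patch_cells Expected patch size in cells (>= 2).
#' @param severity_alpha,severity_beta Beta law for patch severity; defaults
#'   give mean 0.67, the continental mean patch severity.
#' @param severity_jitter_sd SD of the cell-level Gaussian jitter around the
#'   patch severity (clipped to [0, 1]).
#' @param countries,bioregions,in_eu Stratum codes assigned to datasets
#'   (recycled).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return List of class `landscape_config`.
#' @export
landscape_config <- function(nrows = 128L, ncols = 128L, cell_size = 30,
                             year_min = 1986L, year_max = 2020L,
                             severity_year_max = 2016L,
                             forest_cover = 0.7,
                             n_datasets = 3L, polygons_per_dataset = 3L,
                             mapping_years = c(2013L, 2015L, 2017L),
                             statuses = "DOCUMENTED",
                             hazard_pre = 0.0008, hazard_post = 0.0015,
                             anthro_hazard = 0, selection_bias = FALSE,
                             mean_patch_cells = 4,
                             severity_alpha = 6.7, severity_beta = 3.3,
                             severity_jitter_sd = 0.05,
                             countries = c("ALB", "BOR", "CAR"),
                             bioregions = c("Alpine", "Boreal", "Continental"),
                             in_eu = c(TRUE, TRUE, FALSE),
                             seed = 1L) {
  stopifnot(hazard_pre >= 0, hazard_pre <= 1, hazard_post >= 0,
            hazard_post <= 1, anthro_hazard >= 0,
            mean_patch_cells >= 2, forest_cover > 0, forest_cover <= 1)
  n <- as.integer(n_datasets)
  cfg <- list(nrows = as.integer(nrows), ncols = as.integer(ncols),
              cell_size = cell_size, year_min = as.integer(year_min),
              year_max = as.integer(year_max),
              severity_year_max = as.integer(severity_year_max),
              forest_cover = forest_cover, n_datasets = n,
              polygons_per_dataset = as.integer(polygons_per_dataset),
              mapping_years = as.integer(rep_len(mapping_years, n)),
              statuses = toupper(rep_len(statuses, n)),
              hazard_pre = hazard_pre, hazard_post = hazard_post,
              anthro_hazard = anthro_hazard,
              selection_bias = isTRUE(selection_bias),
              mean_patch_cells = mean_patch_cells,
              severity_alpha = severity_alpha, severity_beta = severity_beta,
              severity_jitter_sd = severity_jitter_sd,
              countries = rep_len(countries, n),
              bioregions = rep_len(bioregions, n),
              in_eu = rep_len(in_eu, n), seed = as.integer(seed))
  bad <- cfg$statuses == "DOCUMENTED" &
    (cfg$mapping_years < cfg$year_min | cfg$mapping_years > cfg$year_max)
  if (any(bad)) stop("mapping_years outside the disturbance window", call. = FALSE)
  class(cfg) <- "landscape_config"
  cfg
}

#' Generate a synthetic landscape with known ground truth
#'
#' @param config A [landscape_config()].
#' @return List with `layers` ([disturbance_layers()]), `polygons` (list of
#'   [pf_polygon()]; excluded selection-bias candidates omitted), `datasets`
#'   (dataset table), `truth` (per-dataset data.frame of true hazards,
#'   expected rates `100 * hazard`, true severity mean, mapping years, and
#'   realized pre/post rates), `anthro` (logical matrix marking the labeled
#'   anthropogenic stream) and `excluded_polygons` (character ids dropped by
#'   the selection-bias mode).
#' @export
simulate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  cfg <- config
  set.seed(cfg$seed)
  nr <- cfg$nrows; nc <- cfg$ncols; ncell <- nr * nc
  grid <- pf_grid(nr, nc, cfg$cell_size)
  forest <- matrix(stats::runif(ncell) < cfg$forest_cover, nr, nc)
  year <- matrix(0L, nr, nc)
  severity <- matrix(NA_real_, nr, nc)
  anthro <- matrix(FALSE, nr, nc)

  # rectangular polygon blocks tiling the grid, assigned round-robin to datasets
  npoly <- cfg$n_datasets * cfg$polygons_per_dataset
  nbc <- ceiling(sqrt(npoly)); nbr <- ceiling(npoly / nbc)
  row_b <- floor(seq(0, nr, length.out = nbr + 1L))
  col_b <- floor(seq(0, nc, length.out = nbc + 1L))
  block_of_cell <- integer(ncell)
  poly_defs <- list()
  b <- 0L
  for (br in seq_len(nbr)) for (bc in seq_len(nbc)) {
    if (b >= npoly) next
    b <- b + 1L
    rows <- (row_b[br] + 1L):row_b[br + 1L]
    cols <- (col_b[bc] + 1L):col_b[bc + 1L]
    block_of_cell[rep(rows, length(cols)) + (rep(cols, each = length(rows)) - 1L) * nr] <- b
    # map-coordinate rectangle covering exactly these cells
    x0 <- grid$origin[1] + (min(cols) - 1L) * cfg$cell_size
    x1 <- grid$origin[1] + max(cols) * cfg$cell_size
    y0 <- grid$origin[2] + (nr - max(rows)) * cfg$cell_size
    y1 <- grid$origin[2] + (nr - min(rows) + 1L) * cfg$cell_size
    ds <- (b - 1L) %% cfg$n_datasets + 1L
    poly_defs[[b]] <- list(ds = ds, ring = cbind(c(x0, x1, x1, x0),
                                                 c(y0, y0, y1, y1)))
  }
  ds_of_cell <- ifelse(block_of_cell > 0L,
                       (block_of_cell - 1L) %% cfg$n_datasets + 1L, 0L)
  my_of_cell <- rep(NA_integer_, ncell)
  has_my <- ds_of_cell > 0L & cfg$statuses[pmax(ds_of_cell, 1L)] == "DOCUMENTED"
  my_of_cell[has_my] <- cfg$mapping_years[ds_of_cell[has_my]]
  default_my <- round(mean(cfg$mapping_years[cfg$statuses == "DOCUMENTED"]))
  if (is.na(default_my)) default_my <- cfg$year_max
  my_of_cell[is.na(my_of_cell)] <- default_my

  q <- if (cfg$mean_patch_cells > 2) 1 / (cfg$mean_patch_cells - 1) else 1
  grow_patch <- function(seed_cell, target) {
    cells <- seed_cell
    frontier <- .rook_neighbors(seed_cell, nr, nc)
    while (length(cells) < target) {
      frontier <- frontier[forest[frontier] & year[frontier] == 0L &
                             !(frontier %in% cells)]
      if (!length(frontier)) break
      nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
      cells <- c(cells, nxt)
      frontier <- c(frontier, .rook_neighbors(nxt, nr, nc))
    }
    cells
  }
  paint <- function(cells, y, is_anthro) {
    year[cells] <<- y
    if (is_anthro) anthro[cells] <<- TRUE
    if (y <= cfg$severity_year_max) {
      s <- stats::rbeta(1L, cfg$severity_alpha, cfg$severity_beta)
      severity[cells] <<- pmin(pmax(
        s + stats::rnorm(length(cells), 0, cfg$severity_jitter_sd), 0), 1)
    }
  }
  for (y in cfg$year_min:cfg$year_max) {
    eligible <- which(forest & year == 0L)
    if (!length(eligible)) break
    h <- ifelse(y <= my_of_cell[eligible], cfg$hazard_pre, cfg$hazard_post)
    p_seed <- h / cfg$mean_patch_cells
    u <- stats::runif(length(eligible))
    seeds <- eligible[u < p_seed]
    a_seeds <- integer(0)
    if (cfg$anthro_hazard > 0) {
      pre <- y <= my_of_cell[eligible]
      a_seeds <- eligible[pre & u >= p_seed &
                            u < p_seed + cfg$anthro_hazard / cfg$mean_patch_cells]
    }
    all_seeds <- c(seeds, a_seeds)
    lab <- c(rep(FALSE, length(seeds)), rep(TRUE, length(a_seeds)))
    if (length(all_seeds) > 1L) {
      ord <- sample.int(length(all_seeds))
      all_seeds <- all_seeds[ord]; lab <- lab[ord]
    }
    for (k in seq_along(all_seeds)) {
      sc <- all_seeds[k]
      if (year[sc] != 0L) next
      target <- 2L + stats::rgeom(1L, q)
      paint(grow_patch(sc, target), y, lab[k])
    }
  }

  polygons <- list()
  excluded <- character(0)
  for (b in seq_along(poly_defs)) {
    pd <- poly_defs[[b]]
    ds <- pd$ds
    pid <- sprintf("P%03d", b)
    if (cfg$selection_bias && cfg$statuses[ds] == "DOCUMENTED") {
      cells_b <- which(block_of_cell == b)
      hit <- anthro[cells_b] & year[cells_b] > 0L &
        year[cells_b] <= cfg$mapping_years[ds]
      if (any(hit)) { excluded <- c(excluded, pid); next }
    }
    polygons[[length(polygons) + 1L]] <- pf_polygon(
      pid, sprintf("D%02d", ds), cfg$countries[ds], cfg$bioregions[ds],
      cfg$in_eu[ds], pd$ring)
  }
  datasets <- data.frame(dataset_id = sprintf("D%02d", seq_len(cfg$n_datasets)),
                         status = cfg$statuses,
                         mapping_year = ifelse(cfg$statuses == "DOCUMENTED",
                                               cfg$mapping_years, NA_integer_),
                         stringsAsFactors = FALSE)

  # realized per-dataset rates (per forest cell per year, pre/post windows)
  truth <- do.call(rbind, lapply(seq_len(cfg$n_datasets), function(d) {
    cells_d <- which(ds_of_cell == d)
    fcells <- cells_d[forest[cells_d]]
    my <- cfg$mapping_years[d]
    doc <- cfg$statuses[d] == "DOCUMENTED"
    ny_pre <- my - cfg$year_min + 1L
    ny_post <- cfg$year_max - my
    yrs <- year[fcells]
    data.frame(
      dataset_id = sprintf("D%02d", d), status = cfg$statuses[d],
      mapping_year = if (doc) my else NA_integer_,
      hazard_pre = cfg$hazard_pre, hazard_post = cfg$hazard_post,
      true_rate_pre = 100 * cfg$hazard_pre,
      true_rate_post = 100 * cfg$hazard_post,
      true_severity_mean = cfg$severity_alpha /
        (cfg$severity_alpha + cfg$severity_beta),
      realized_rate_pre = if (doc && ny_pre > 0)
        100 * sum(yrs > 0 & yrs <= my) / (length(fcells) * ny_pre) else NA_real_,
      realized_rate_post = if (doc && ny_post > 0)
        100 * sum(yrs > my) / (length(fcells) * ny_post) else NA_real_,
      stringsAsFactors = FALSE)
  }))

  layers <- disturbance_layers(grid, year, severity, forest,
                               year_min = cfg$year_min, year_max = cfg$year_max,
                               severity_year_max = cfg$severity_year_max)
  list(layers = layers, polygons = polygons, datasets = datasets,
       truth = truth, anthro = anthro, excluded_polygons = excluded,
       config = cfg)
}

.rook_neighbors <- function(cell, nr, nc) {
  r <- (cell - 1L) %% nr + 1L
  cc <- (cell - 1L) %/% nr + 1L
  out <- integer(0)
  if (r > 1L) out <- c(out, cell - 1L)
  if (r < nr) out <- c(out, cell + 1L)
  if (cc > 1L) out <- c(out, cell - nr)
  if (cc < nc) out <- c(out, cell + nr)
  out
}

#' Write a synthetic bundle to disk in the package's exchange formats
#'
#' Emits year/severity/forest ESRI ASCII grids, a GeoJSON polygon layer, the
#' dataset CSV and the truth table CSV.
#'
#' @param sim Result of [simulate_landscape()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written.
#' @export
write_landscape <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(year = file.path(dir, "disturbance_year.asc"),
             severity = file.path(dir, "disturbance_severity.asc"),
             forest = file.path(dir, "forest_mask.asc"),
             polygons = file.path(dir, "polygons.geojson"),
             datasets = file.path(dir, "datasets.csv"),
             truth = file.path(dir, "truth.csv"))
  write_layers(sim$layers, paths["year"], paths["severity"], paths["forest"])
  write_polygons(sim$polygons, paths["polygons"])
  utils::write.csv(sim$datasets, paths["datasets"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  paths
}
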