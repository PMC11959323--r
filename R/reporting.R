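#' Run configuration
#'
#' Reads (or validates) the structured run configuration driving the
#' command-style entry points [run_simulate()], [run_assess()] and
#' [run_compare()]. Defaults echo the study configuration: window 1986-2020,
#' severity to 2016, MMU 2 cells, 10,000 bootstrap iterations, 95% CIs,
#' 1000-patch Mann-Whitney cap, sensitivity shifts -3..+3.
#'
#' @param x Path to a YAML file, or a named list of settings.
#' @return List of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    year_path = NULL, severity_path = NULL, forest_path = NULL,
    polygons_path = NULL, datasets_path = NULL, reported_path = NULL,
    out_dir = ".", seed = 1L,
    year_min = 1986L, year_max = 2020L, severity_year_max = 2016L,
    min_cells = 2L, n_iter = 10000L, level = 0.95, mw_max_n = 1000L,
    count_variation = TRUE, shifts = -3:3, simulate = list())
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, x)
  if (cfg$min_cells < 1L) stop("min_cells must be >= 1", call. = FALSE)
  if (cfg$level <= 0 || cfg$level >= 1) stop("level must be in (0,1)", call. = FALSE)
  structure(cfg, class = "run_config")
}

.cfg_paths_exist <- function(cfg, keys) {
  for (k in keys) {
    p <- cfg[[k]]
    if (is.null(p)) stop("config key '", k, "' is required", call. = FALSE)
    if (!file.exists(p)) stop("file not found for '", k, "': ", p, call. = FALSE)
  }
}

#' Generate a synthetic bundle on disk
#'
#' Wraps [simulate_landscape()]/[write_landscape()]; generator settings come
#' from the config's `simulate` sub-list (passed to [landscape_config()]),
#' with the run seed.
#'
#' @param cfg A [run_config()] (or path/list coercible to one).
#' @return Named vector of files written (invisibly).
#' @export
run_simulate <- function(cfg) {
  cfg <- run_config(cfg)
  lc <- do.call(landscape_config, utils::modifyList(cfg$simulate,
                                                    list(seed = cfg$seed)))
  sim <- simulate_landscape(lc)
  invisible(write_landscape(sim, cfg$out_dir))
}

#' Run the full assessment from files and write the output tables
#'
#' Reads the rasters, polygon layer and dataset table named in the config,
#' runs [assess_disturbance()] and writes `indicators.csv`, `severity.csv`,
#' `tests.csv`, `sensitivity.csv` and `polygons.csv` into `out_dir`, each with
#' a `# pfdisturb:` header line echoing seed and bootstrap settings. An empty
#' polygon layer yields empty tables with a warning, not an error.
#'
#' @param cfg A [run_config()].
#' @return The `pf_assessment`, invisibly.
#' @export
run_assess <- function(cfg) {
  cfg <- run_config(cfg)
  .cfg_paths_exist(cfg, c("year_path", "severity_path", "forest_path",
                          "polygons_path", "datasets_path"))
  layers <- read_layers(cfg$year_path, cfg$severity_path, cfg$forest_path,
                        cfg$year_min, cfg$year_max, cfg$severity_year_max)
  polygons <- read_polygons(cfg$polygons_path)
  datasets <- read_dataset_table(cfg$datasets_path, cfg$year_min, cfg$year_max)
  if (length(polygons) == 0L) {
    warning("empty polygon layer; writing empty tables", call. = FALSE)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("indicators", "severity", "tests", "sensitivity", "polygons"))
      .write_table(data.frame(), file.path(cfg$out_dir, paste0(nm, ".csv")), cfg)
    return(invisible(NULL))
  }
  a <- assess_disturbance(
    layers, polygons, datasets, min_cells = cfg$min_cells,
    spec = boot_spec(cfg$n_iter, cfg$level,
                     count_variation = cfg$count_variation),
    mw_max_n = cfg$mw_max_n, shifts = cfg$shifts, seed = cfg$seed)
  write_assessment(a, cfg$out_dir, cfg)
  invisible(a)
}

#' Write the assessment tables as CSV
#'
#' @param a A `pf_assessment`.
#' @param dir Output directory.
#' @param cfg Optional [run_config()] echoed in the header lines.
#' @export
write_assessment <- function(a, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_table(a$indicators, file.path(dir, "indicators.csv"), cfg, a)
  .write_table(a$severity, file.path(dir, "severity.csv"), cfg, a)
  .write_table(a$tests %||% data.frame(), file.path(dir, "tests.csv"), cfg, a)
  .write_table(a$sensitivity %||% data.frame(),
               file.path(dir, "sensitivity.csv"), cfg, a)
  .write_table(a$polygons, file.path(dir, "polygons.csv"), cfg, a)
  invisible(dir)
}

.write_table <- function(d, path, cfg = NULL, a = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- if (!is.null(a)) a$meta$seed else if (!is.null(cfg)) cfg$seed else NA
  n_iter <- if (!is.null(a)) a$meta$spec$n_iter else
    if (!is.null(cfg)) cfg$n_iter else NA
  writeLines(sprintf("# pfdisturb: seed=%s n_iter=%s generated=%s",
                     seed %||% "NULL", n_iter,
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_assessment()]
#'
#' Skips the `# pfdisturb:` header line (excluded from any byte comparison).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_assessment_table <- function(path) {
  tryCatch(utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
           error = function(e) data.frame())
}

#' Country-level comparison against reported areas
#'
#' Runs the assessment inputs through [combined_area()]/[discrepancy()]
#' against the reported-area CSV (`country`, `reported_area_ha`) and writes
#' `discrepancy.csv`. The differing forest definitions behind mapped and
#' reported areas limit comparability; the output is a screening table, not a
#' validation.
#'
#' @param cfg A [run_config()]; needs an `indicators.csv` already present in
#'   `out_dir` (or run [run_assess()] first) and `reported_path`.
#' @return The discrepancy table, invisibly.
#' @export
run_compare <- function(cfg) {
  cfg <- run_config(cfg)
  .cfg_paths_exist(cfg, "reported_path")
  ind_path <- file.path(cfg$out_dir, "indicators.csv")
  if (!file.exists(ind_path))
    stop("indicators.csv not found in out_dir; run run_assess() first",
         call. = FALSE)
  ind <- read_assessment_table(ind_path)
  rep_tab <- utils::read.csv(cfg$reported_path, stringsAsFactors = FALSE)
  d <- discrepancy(combined_area(ind), rep_tab)
  .write_table(d, file.path(cfg$out_dir, "discrepancy.csv"), cfg)
  invisible(d)
}
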