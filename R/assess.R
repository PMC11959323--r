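#' Assess disturbances in primary and potential primary forest polygons
#'
#' The full assessment chain: MMU-filter the forest mask, delineate and
#' MMU-filter annual disturbance patches by rook contiguity, rasterize the
#' polygon layers, attribute each disturbed cell to the period predating or
#' postdating its dataset's mapping year (documented polygons) or to the full
#' window (potential polygons), and aggregate the three indicators - total
#' area disturbed, proportion of area disturbed, mean annual rate of area
#' disturbed - plus patch-level mean disturbance severity at the country,
#' biogeographical-region, EU and continental level. Bootstrap percentile
#' confidence intervals, a bootstrap rate-difference test, the subsampled
#' Mann-Whitney severity test and a mapping-year sensitivity analysis round
#' out the result.
#'
#' Disturbed cells are counted only where they intersect both the polygon and
#' the MMU-filtered forest mask, matching the mask-based denominator.
#' Overlaps between documented and potential polygons are resolved in favor of
#' the documented layer (potential cells clipped). Aggregated rates are
#' recomputed from pooled areas - `100 * sum(disturbed) / sum(forest_ha *
#' n_years)` over member polygons - never by averaging dataset-level rates.
#' For severity, a patch belongs to a polygon's stratum if any of its cells
#' lies inside the polygon, its mean is taken over all its cells, and it is
#' counted once per stratum (period attributed via the polygon with the
#' largest overlap; ties broken by lowest polygon_id).
#'
#' @param layers A [disturbance_layers()].
#' @param polygons List of [pf_polygon()].
#' @param datasets Dataset table (data.frame with dataset_id, status,
#'   mapping_year), see [read_dataset_table()].
#' @param min_cells Minimum mapping unit in cells (default 2, i.e. 0.18 ha at
#'   30 m), applied to disturbance and forest patches alike.
#' @param spec A [boot_spec()] controlling all bootstrap computations.
#' @param mw_max_n Subsampling cap for the Mann-Whitney severity test.
#' @param shifts Signed mapping-year shifts for the sensitivity analysis.
#' @param seed Master seed; all resampling sub-seeds derive from it.
#' @param compute_ci,compute_tests Switch off the bootstrap CIs / tests for
#'   fast point-estimate-only runs.
#' @return Object of class `pf_assessment` with elements `indicators`,
#'   `severity`, `tests`, `sensitivity`, `polygons` (per-polygon table),
#'   `patches`, `weighted_mapping_year`, `meta`.
#' @export
assess_disturbance <- function(layers, polygons, datasets, min_cells = 2L,
                               spec = boot_spec(), mw_max_n = 1000L,
                               shifts = -3:3, seed = NULL,
                               compute_ci = TRUE, compute_tests = TRUE) {
  stopifnot(inherits(layers, "disturbance_layers"))
  datasets <- validate_dataset_table(datasets, layers$year_min, layers$year_max)
  seed <- seed %||% spec$seed
  sub_seed <- local({ counter <- 0L; function() {
    if (is.null(seed)) return(NULL)
    counter <<- counter + 1L
    as.integer((as.numeric(seed) + 77777 * counter) %% 2147483647)
  }})
  g <- layers$grid
  aha <- cell_area_ha(g)
  years <- layers$year_min:layers$year_max

  mask <- filtered_forest_mask(layers, min_cells)
  patches <- apply_mmu(label_patches(layers, "disturbance"), min_cells)
  pcells <- attr(patches, "cells")
  pidr <- matrix(0L, g$nrows, g$ncols)
  for (i in seq_along(pcells)) pidr[pcells[[i]]] <- i

  # rasterize polygons; clip potential under documented
  ds_idx <- match(vapply(polygons, `[[`, character(1), "dataset_id"),
                  datasets$dataset_id)
  if (anyNA(ds_idx))
    stop("polygon references unknown dataset_id", call. = FALSE)
  status <- datasets$status[ds_idx]
  cells_list <- lapply(polygons, rasterize_polygon, grid = g)
  doc_occupied <- logical(g$nrows * g$ncols)
  for (i in which(status == "DOCUMENTED")) doc_occupied[cells_list[[i]]] <- TRUE
  for (i in which(status == "POTENTIAL"))
    cells_list[[i]] <- cells_list[[i]][!doc_occupied[cells_list[[i]]]]

  npoly <- length(polygons)
  ycounts <- matrix(0L, npoly, length(years), dimnames = list(NULL, years))
  pairs <- vector("list", npoly)       # area pairs: patch x polygon (masked)
  sev_pairs <- vector("list", npoly)   # membership pairs: any cell in polygon
  poly <- data.frame(
    polygon_id = vapply(polygons, `[[`, character(1), "polygon_id"),
    dataset_id = vapply(polygons, `[[`, character(1), "dataset_id"),
    country = vapply(polygons, `[[`, character(1), "country"),
    bioregion = vapply(polygons, `[[`, character(1), "bioregion"),
    in_eu = vapply(polygons, `[[`, logical(1), "in_eu"),
    status = status, mapping_year = datasets$mapping_year[ds_idx],
    stringsAsFactors = FALSE)
  poly$polygon_area_ha <- lengths(cells_list) * aha
  poly$fcells <- 0L
  poly$cells_pre <- poly$cells_post <- NA_integer_
  poly$cells_full <- 0L

  for (i in seq_len(npoly)) {
    cp <- cells_list[[i]]
    fcells <- cp[mask[cp]]
    poly$fcells[i] <- length(fcells)
    dc <- fcells[pidr[fcells] > 0L]
    yr <- layers$year[dc]
    pid <- pidr[dc]
    if (length(yr)) {
      tab <- table(factor(yr, levels = years))
      ycounts[i, ] <- as.integer(tab)
    }
    my <- poly$mapping_year[i]
    poly$cells_full[i] <- length(dc)
    if (!is.na(my)) {
      poly$cells_pre[i] <- sum(yr <= my)
      poly$cells_post[i] <- poly$cells_full[i] - poly$cells_pre[i]
    }
    if (length(pid)) {
      cnt <- tapply(rep(1L, length(pid)), pid, sum)
      pids <- as.integer(names(cnt))
      pairs[[i]] <- data.frame(poly = i, pid = pids,
                               cells = as.integer(cnt),
                               year = patches$year[pids])
    }
    # severity membership: any polygon cell (mask-independent)
    spid <- pidr[cp]
    spid <- spid[spid > 0L]
    if (length(spid)) {
      scnt <- tapply(rep(1L, length(spid)), spid, sum)
      sev_pairs[[i]] <- data.frame(poly = i,
                                   pid = as.integer(names(scnt)),
                                   overlap = as.integer(scnt))
    }
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  sev_pairs <- do.call(rbind, sev_pairs[!vapply(sev_pairs, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(poly = integer(0), pid = integer(0),
                        cells = integer(0), year = integer(0))
  if (is.null(sev_pairs))
    sev_pairs <- data.frame(poly = integer(0), pid = integer(0),
                            overlap = integer(0))

  pl <- lapply(poly$mapping_year, period_lengths, layers$year_min, layers$year_max)
  poly$nyears_pre <- vapply(pl, function(x) as.numeric(x$PRE %||% NA), numeric(1))
  poly$nyears_post <- vapply(pl, function(x) as.numeric(x$POST %||% NA), numeric(1))
  poly$nyears_full <- layers$year_max - layers$year_min + 1L
  poly$forest_ha <- poly$fcells * aha
  poly$dist_pre <- poly$cells_pre * aha
  poly$dist_post <- poly$cells_post * aha
  poly$dist_full <- poly$cells_full * aha

  strata <- .build_strata(poly)
  records <- .aggregate_records(poly, strata, aha)

  # per-record patch area values (clipped to the stratum), for CIs and tests
  patch_values <- function(member, status, period) {
    pp <- pairs[member[pairs$poly] & poly$status[pairs$poly] == status, ,
                drop = FALSE]
    if (period %in% c("PRE", "POST") && nrow(pp)) {
      my <- poly$mapping_year[pp$poly]
      is_pre <- pp$year <= my
      pp <- pp[if (period == "PRE") is_pre else !is_pre, , drop = FALSE]
    }
    if (!nrow(pp)) return(numeric(0))
    as.numeric(tapply(pp$cells, pp$pid, sum)) * aha
  }
  member_of <- function(stype, scode) switch(stype,
    country = poly$country == scode, bioregion = poly$bioregion == scode,
    eu = poly$in_eu, europe = rep(TRUE, nrow(poly)))

  records$n_patches <- NA_integer_
  records$area_ci_lo <- records$area_ci_hi <- NA_real_
  records$rate_ci_lo <- records$rate_ci_hi <- NA_real_
  for (k in seq_len(nrow(records))) {
    member <- member_of(records$stratum_type[k], records$stratum[k])
    v <- patch_values(member, records$status[k], records$period[k])
    records$n_patches[k] <- length(v)
    if (!compute_ci) next
    if (length(v) == 0L) {
      records$area_ci_lo[k] <- records$area_ci_hi[k] <- 0
      next
    }
    ci <- bootstrap_ci(v, "total",
                       spec = .respec(spec, sub_seed()))
    records$area_ci_lo[k] <- ci[1]; records$area_ci_hi[k] <- ci[2]
    rows <- poly[member & poly$status == records$status[k], , drop = FALSE]
    denom <- sum(as.numeric(rows$fcells) *
                   rows[[paste0("nyears_", tolower(records$period[k]))]]) * aha
    if (!is.na(denom) && denom > 0) {
      ci <- bootstrap_ci(v, "rate", spec = .respec(spec, sub_seed()),
                         denom = denom)
      records$rate_ci_lo[k] <- ci[1]; records$rate_ci_hi[k] <- ci[2]
    }
  }

  # severity summaries: one patch counted once per stratum; period by the
  # polygon with the largest overlap (ties: lowest polygon_id)
  sev_values <- function(member, status, period) {
    sp <- sev_pairs[member[sev_pairs$poly] &
                      poly$status[sev_pairs$poly] == status, , drop = FALSE]
    if (!nrow(sp)) return(numeric(0))
    ord <- order(sp$pid, -sp$overlap, poly$polygon_id[sp$poly])
    sp <- sp[ord, , drop = FALSE]
    sp <- sp[!duplicated(sp$pid), , drop = FALSE]
    eligible <- patches$year[sp$pid] <= layers$severity_year_max &
      isTRUE_v(patches$severity_valid[sp$pid])
    sp <- sp[eligible, , drop = FALSE]
    if (period %in% c("PRE", "POST") && nrow(sp)) {
      my <- poly$mapping_year[sp$poly]
      is_pre <- patches$year[sp$pid] <= my
      sp <- sp[if (period == "PRE") is_pre else !is_pre, , drop = FALSE]
    }
    patches$mean_severity[sp$pid]
  }
  sev_rows <- list()
  for (k in seq_len(nrow(records))) {
    member <- member_of(records$stratum_type[k], records$stratum[k])
    v <- sev_values(member, records$status[k], records$period[k])
    s <- stratum_mean_severity(v)
    ci <- c(NA_real_, NA_real_)
    if (compute_ci && s$n_patches >= 1L)
      ci <- suppressWarnings(
        bootstrap_ci(v, "mean", spec = .respec(spec, sub_seed())))
    sev_rows[[k]] <- data.frame(
      stratum_type = records$stratum_type[k], stratum = records$stratum[k],
      status = records$status[k], period = records$period[k],
      n_patches = s$n_patches, n_excluded = s$n_excluded,
      mean_severity = s$mean, sev_ci_lo = ci[1], sev_ci_hi = ci[2])
  }
  severity <- do.call(rbind, sev_rows)

  tests <- NULL
  if (compute_tests) {
    tl <- list()
    us <- unique(records[records$status == "DOCUMENTED",
                         c("stratum_type", "stratum")])
    for (k in seq_len(nrow(us))) {
      member <- member_of(us$stratum_type[k], us$stratum[k])
      rows <- poly[member & poly$status == "DOCUMENTED", , drop = FALSE]
      if (!nrow(rows)) next
      pre_v <- patch_values(member, "DOCUMENTED", "PRE")
      post_v <- patch_values(member, "DOCUMENTED", "POST")
      denom_pre <- sum(as.numeric(rows$fcells) * rows$nyears_pre) * aha
      denom_post <- sum(as.numeric(rows$fcells) * rows$nyears_post) * aha
      rd <- suppressWarnings(
        rate_difference_test(pre_v, post_v, denom_pre, denom_post,
                             spec = .respec(spec, sub_seed())))
      sev_pre <- sev_values(member, "DOCUMENTED", "PRE")
      sev_post <- sev_values(member, "DOCUMENTED", "POST")
      sev_pre <- sev_pre[!is.na(sev_pre)]; sev_post <- sev_post[!is.na(sev_post)]
      mw_p <- NA_real_; mw_u <- NA_real_
      if (length(sev_pre) && length(sev_post)) {
        mw <- mann_whitney_severity_test(sort(sev_pre), sort(sev_post),
                                         max_n = mw_max_n, seed = sub_seed())
        mw_p <- mw$p_value; mw_u <- mw$statistic
      }
      tl[[length(tl) + 1L]] <- data.frame(
        stratum_type = us$stratum_type[k], stratum = us$stratum[k],
        rate_change = rd$statistic, rate_p = rd$p_value,
        rate_flag = significance_flag(rd$p_value),
        n_pre = rd$n_pre, n_post = rd$n_post,
        mw_U = mw_u, severity_p = mw_p,
        severity_flag = significance_flag(mw_p),
        n_sev_pre = length(sev_pre), n_sev_post = length(sev_post))
    }
    tests <- if (length(tl)) do.call(rbind, tl) else NULL
  }

  wmy <- tryCatch(
    weighted_mean_mapping_year(poly$mapping_year, poly$polygon_area_ha),
    error = function(e) NA_real_)

  out <- structure(list(
    indicators = records, severity = severity, tests = tests,
    polygons = poly, patches = patches, ycounts = ycounts,
    weighted_mapping_year = wmy,
    meta = list(min_cells = min_cells, spec = spec, mw_max_n = mw_max_n,
                seed = seed, shifts = shifts,
                year_min = layers$year_min, year_max = layers$year_max,
                severity_year_max = layers$severity_year_max,
                cell_area_ha = aha)),
    class = "pf_assessment")
  out$sensitivity <- sensitivity_analysis(out, shifts)
  out
}

isTRUE_v <- function(x) !is.na(x) & x

.respec <- function(spec, seed) { spec$seed <- seed; spec }

.build_strata <- function(poly) {
  s <- rbind(
    data.frame(stratum_type = "country",
               stratum = sort(unique(poly$country))),
    data.frame(stratum_type = "bioregion",
               stratum = sort(unique(poly$bioregion))),
    if (any(poly$in_eu)) data.frame(stratum_type = "eu", stratum = "EU"),
    data.frame(stratum_type = "europe", stratum = "EUROPE"))
  rownames(s) <- NULL
  s
}

#' Mapping-year sensitivity analysis
#'
#' Recomputes the predating/postdating mean annual rates and the rate change
#' for every stratum with each dataset's mapping year shifted by a signed
#' number of years (shifted years are clamped to the disturbance window).
#' Shift 0 reproduces the baseline rates exactly.
#'
#' @param assessment A `pf_assessment`.
#' @param shifts Integer vector of signed year shifts (default -3..+3, seven
#'   values).
#' @return data.frame: stratum x shift with `rate_pre`, `rate_post`,
#'   `rate_change`.
#' @export
sensitivity_analysis <- function(assessment, shifts = -3:3) {
  stopifnot(inherits(assessment, "pf_assessment"))
  poly <- assessment$polygons
  ycounts <- assessment$ycounts
  meta <- assessment$meta
  years <- meta$year_min:meta$year_max
  aha <- meta$cell_area_ha
  doc <- which(poly$status == "DOCUMENTED")
  if (!length(doc)) return(NULL)
  strata <- .build_strata(poly)
  out <- list()
  for (sh in as.integer(shifts)) {
    my <- pmin(pmax(poly$mapping_year + sh, meta$year_min), meta$year_max)
    pre_cells <- vapply(seq_len(nrow(poly)), function(i) {
      if (is.na(my[i])) return(NA_integer_)
      sum(ycounts[i, years <= my[i]])
    }, integer(1))
    full_cells <- as.integer(rowSums(ycounts))
    ny_pre <- as.numeric(my - meta$year_min + 1L)
    ny_post <- as.numeric(meta$year_max - my)
    for (si in seq_len(nrow(strata))) {
      member <- switch(strata$stratum_type[si],
        country = poly$country == strata$stratum[si],
        bioregion = poly$bioregion == strata$stratum[si],
        eu = poly$in_eu, europe = rep(TRUE, nrow(poly)))
      idx <- which(member & poly$status == "DOCUMENTED")
      if (!length(idx)) next
      # counts first, hectares once: bit-identical to the indicator records
      dist_pre <- sum(pre_cells[idx]) * aha
      dist_post <- sum(full_cells[idx] - pre_cells[idx]) * aha
      den_pre <- sum(as.numeric(poly$fcells[idx]) * ny_pre[idx]) * aha
      den_post <- sum(as.numeric(poly$fcells[idx]) * ny_post[idx]) * aha
      r_pre <- if (den_pre > 0) 100 * dist_pre / den_pre else NA_real_
      r_post <- if (den_post > 0) 100 * dist_post / den_post else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        stratum_type = strata$stratum_type[si], stratum = strata$stratum[si],
        shift = sh, rate_pre = r_pre, rate_post = r_post,
        rate_change = r_post - r_pre)
    }
  }
  do.call(rbind, out)
}

#' @export
print.pf_assessment <- function(x, ...) {
  ind <- x$indicators
  cat(sprintf("<pf_assessment> %d polygons, %d patches | window %d-%d\n",
              nrow(x$polygons), nrow(x$patches),
              x$meta$year_min, x$meta$year_max))
  eu <- ind[ind$stratum_type == "europe", , drop = FALSE]
  for (k in seq_len(nrow(eu)))
    cat(sprintf("  %-9s %-4s forest %.1f ha | disturbed %.2f ha (%.2f%%) | rate %s %%/yr\n",
                eu$status[k], eu$period[k], eu$forest_area_ha[k],
                eu$disturbed_area_ha[k], eu$proportion_pct[k],
                ifelse(is.na(eu$rate_pct_yr[k]), "NA",
                       sprintf("%.3f", eu$rate_pct_yr[k]))))
  invisible(x)
}

#' @export
summary.pf_assessment <- function(object, ...) {
  structure(list(indicators = object$indicators, severity = object$severity,
                 tests = object$tests,
                 weighted_mapping_year = object$weighted_mapping_year),
            class = "summary.pf_assessment")
}

#' @export
print.summary.pf_assessment <- function(x, ...) {
  cat("Indicator records:\n")
  print(x$indicators, digits = 4)
  cat(sprintf("\nArea-weighted mean mapping year: %s\n",
              ifelse(is.na(x$weighted_mapping_year), "NA",
                     sprintf("%.1f", x$weighted_mapping_year))))
  if (!is.null(x$tests)) {
    cat("\nRate-difference and severity tests (** p<0.05, * p<0.10):\n")
    print(x$tests, digits = 4)
  }
  invisible(x)
}
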