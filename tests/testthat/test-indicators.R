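test_that("period attribution puts the mapping year itself in the predating period", {
  expect_equal(attribute_period(2015, 2015), "PRE")
  expect_equal(attribute_period(1990, 2015), "PRE")
  expect_equal(attribute_period(2016, 2015), "POST")
  expect_equal(attribute_period(c(1986, 2015, 2016, 2020), 2015),
               c("PRE", "PRE", "POST", "POST"))
  expect_error(attribute_period(1970, 2015), "attribution error")
  expect_error(attribute_period(2000, 2025), "attribution error")
})

test_that("period window lengths include the mapping year in PRE", {
  pl <- period_lengths(2015L)
  expect_equal(pl$PRE, 30L)   # 1986..2015
  expect_equal(pl$POST, 5L)   # 2016..2020
  expect_equal(pl$FULL, 35L)
  expect_equal(period_lengths(2020L)$POST, 0L)
  expect_equal(period_lengths(NA)$FULL, 35L)
})

test_that("polygon forest area counts masked cells times cell area", {
  g <- pf_grid(10, 10, 30)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(polygon_forest_area(1:100, mask, g), 9.0)
  expect_equal(polygon_forest_area(1:50, !mask, g), 0)
  set.seed(8)
  for (i in 1:10) {
    mask <- matrix(runif(100) < 0.6, 10, 10)
    cells <- sample(1:100, sample(1:100, 1))
    manual <- sum(vapply(cells, function(cl) mask[cl], logical(1))) * 0.09
    expect_equal(polygon_forest_area(cells, mask, g), manual)
  }
})

test_that("disturbed area splits by period and is conserved", {
  y <- matrix(0L, 10, 10)
  y[1:2, 1:5] <- 2010L   # 10 cells
  y[5, 1:5] <- 2018L     # 5 cells
  lay <- make_layers(y)
  mask <- matrix(TRUE, 10, 10)
  got <- disturbed_area_by_period(1:100, lay, mask, 2015L)
  expect_equal(got[["PRE"]], 0.9)
  expect_equal(got[["POST"]], 0.45)
  expect_equal(got[["FULL"]], 1.35)
  # potential (no mapping year): everything in FULL
  got_full <- disturbed_area_by_period(1:100, lay, mask, NA)
  expect_equal(got_full[["FULL"]], 1.35)
  # random landscapes: equals the brute-force cell-by-cell double loop,
  # and PRE + POST == FULL always
  set.seed(31)
  for (i in 1:10) {
    y <- matrix(sample(c(0L, 1990L, 2014L, 2016L, 2020L), 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) < 0.7, 8, 8)
    lay <- make_layers(y)
    cells <- sample(1:64, 40)
    my <- sample(1990:2019, 1)
    got <- disturbed_area_by_period(cells, lay, mask, my)
    pre <- post <- 0
    for (cl in cells) if (mask[cl] && y[cl] != 0L) {
      if (y[cl] <= my) pre <- pre + 0.09 else post <- post + 0.09
    }
    expect_equal(got[["PRE"]], pre)
    expect_equal(got[["POST"]], post)
    expect_equal(got[["PRE"]] + got[["POST"]], got[["FULL"]])
  }
})

test_that("proportion and annual rate reproduce the headline arithmetic", {
  expect_equal(round(proportion_disturbed(61836, 2401000), 1), 2.6)
  expect_equal(round(proportion_disturbed(14388, 2401000), 1), 0.6)
  expect_equal(proportion_disturbed(0, 1000), 0)
  expect_true(is.na(proportion_disturbed(5, 0)))
  expect_equal(annual_rate(1, 100, 10), 0.1)
  expect_equal(annual_rate(0, 100, 10), 0)
  expect_error(annual_rate(1, 100, 0), "n_years")
})

test_that("rate and severity changes are plain differences", {
  expect_equal(rate_change(0.08, 0.32), 0.24)   # Alpine
  expect_equal(rate_change(0.08, 0.15), 0.07)   # continental total
  expect_equal(rate_change(0.5, 0.5), 0)
  expect_equal(severity_change(0.63, 0.64), 0.01)
  expect_equal(severity_change(0.69, 0.68), -0.01)
})

test_that("weighted mean mapping year is the area-weighted average", {
  expect_equal(weighted_mean_mapping_year(2015, 10), 2015)
  expect_equal(weighted_mean_mapping_year(c(2010, 2020), c(5, 5)), 2015)
  expect_equal(weighted_mean_mapping_year(c(2000, 2020), c(1, 3)), 2015)
  expect_error(weighted_mean_mapping_year(c(NA, NA), c(1, 1)), "positive area")
})

test_that("aggregation pools areas and recomputes ratios, never averages rates", {
  sim <- fixture_sim()
  a <- assess_disturbance(sim$layers, sim$polygons, sim$datasets,
                          compute_ci = FALSE, compute_tests = FALSE)
  ind <- a$indicators
  for (per in c("PRE", "POST")) {
    cc <- ind[ind$stratum_type == "country" & ind$period == per, ]
    eu <- ind[ind$stratum_type == "europe" & ind$period == per, ]
    expect_equal(sum(cc$disturbed_area_ha), eu$disturbed_area_ha)
    expect_equal(sum(cc$forest_area_ha), eu$forest_area_ha)
    expect_equal(eu$proportion_pct,
                 100 * eu$disturbed_area_ha / eu$forest_area_ha)
  }
  # PRE + POST disturbed area equals the full-window total per polygon
  expect_identical(a$polygons$cells_pre + a$polygons$cells_post,
                   a$polygons$cells_full)
  expect_equal(a$polygons$dist_pre + a$polygons$dist_post,
               a$polygons$dist_full)
})

test_that("a one-country continent reproduces that country's record", {
  sim <- fixture_sim(countries = "AAA", bioregions = "Boreal", in_eu = TRUE)
  a <- assess_disturbance(sim$layers, sim$polygons, sim$datasets,
                          compute_ci = FALSE, compute_tests = FALSE)
  ind <- a$indicators
  for (per in c("PRE", "POST")) {
    cc <- ind[ind$stratum_type == "country" & ind$period == per, ]
    eu <- ind[ind$stratum_type == "europe" & ind$period == per, ]
    expect_equal(cc$disturbed_area_ha, eu$disturbed_area_ha)
    expect_equal(cc$rate_pct_yr, eu$rate_pct_yr)
  }
})

test_that("stratum rates are invariant to splitting polygons", {
  sim <- fixture_sim(seed = 5)
  lay <- sim$layers
  ds <- data.frame(dataset_id = "D1", status = "DOCUMENTED",
                   mapping_year = 2012L)
  ext <- lay$grid$nrows * lay$grid$cell_size
  whole <- list(pf_polygon("W", "D1", "XX", "Alpine", TRUE,
                           rect_ring(0, 0, ext, ext)))
  halves <- list(
    pf_polygon("H1", "D1", "XX", "Alpine", TRUE, rect_ring(0, 0, ext / 2, ext)),
    pf_polygon("H2", "D1", "XX", "Alpine", TRUE, rect_ring(ext / 2, 0, ext, ext)))
  a1 <- assess_disturbance(lay, whole, ds, compute_ci = FALSE,
                           compute_tests = FALSE)
  a2 <- assess_disturbance(lay, halves, ds, compute_ci = FALSE,
                           compute_tests = FALSE)
  e1 <- a1$indicators[a1$indicators$stratum_type == "europe", ]
  e2 <- a2$indicators[a2$indicators$stratum_type == "europe", ]
  expect_equal(e1$rate_pct_yr, e2$rate_pct_yr)
  expect_equal(e1$disturbed_area_ha, e2$disturbed_area_ha)
  expect_equal(e1$forest_area_ha, e2$forest_area_ha)
})

test_that("potential polygons are clipped under documented ones and use FULL", {
  y <- matrix(0L, 6, 6); y[1:2, 1] <- 2010L; y[5:6, 6] <- 2018L
  lay <- make_layers(y)
  ds <- data.frame(dataset_id = c("D1", "D2"),
                   status = c("DOCUMENTED", "POTENTIAL"),
                   mapping_year = c(2015L, NA))
  ext <- 6 * 30
  polys <- list(
    pf_polygon("doc", "D1", "XX", "Alpine", TRUE, rect_ring(0, 0, ext / 2, ext)),
    # potential polygon covering the whole grid: left half must be clipped away
    pf_polygon("pot", "D2", "XX", "Alpine", TRUE, rect_ring(0, 0, ext, ext)))
  a <- assess_disturbance(lay, polys, ds, compute_ci = FALSE,
                          compute_tests = FALSE)
  pot <- a$polygons[a$polygons$polygon_id == "pot", ]
  expect_equal(pot$polygon_area_ha, 18 * 0.09)     # right half only
  expect_equal(pot$dist_full, 2 * 0.09)            # the 2018 patch
  doc <- a$polygons[a$polygons$polygon_id == "doc", ]
  expect_equal(doc$dist_pre, 2 * 0.09)
  expect_equal(doc$dist_post, 0)
  ind <- a$indicators
  expect_setequal(ind$period[ind$status == "POTENTIAL"], "FULL")
})
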