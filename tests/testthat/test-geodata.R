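test_that("cell area follows the unit conversion and scales quadratically", {
  expect_equal(cell_area_ha(pf_grid(4, 4, 30)), 0.09)
  expect_equal(cell_area_ha(pf_grid(4, 4, 100)), 1.0)
  expect_equal(cell_area_ha(pf_grid(4, 4, 10)), 0.01)
  for (cs in c(5, 30, 250))
    expect_equal(cell_area_ha(pf_grid(2, 2, 2 * cs)),
                 4 * cell_area_ha(pf_grid(2, 2, cs)))
  expect_error(pf_grid(4, 4, 0), "cell_size")
  expect_error(pf_grid(0, 4), "nrows")
  expect_warning(pf_grid(4, 4, 30, crs_tag = "EPSG:4326"), "geographic")
})

test_that("rasterization uses cell centers with the lower-left edge rule", {
  g <- pf_grid(4, 4, 30)
  full <- pf_polygon("a", "d", "XX", "Alpine", TRUE, rect_ring(0, 0, 120, 120))
  expect_equal(rasterize_polygon(full, g), 1:16)
  away <- pf_polygon("b", "d", "XX", "Alpine", TRUE,
                     rect_ring(500, 500, 600, 600))
  expect_length(rasterize_polygon(away, g), 0)
  # left half: boundary falls on the column-2/3 cell edge; the 8 left cells
  # (columns 1-2, linear indices 1..8) have centers at x = 15, 45 < 60
  left <- pf_polygon("c", "d", "XX", "Alpine", TRUE, rect_ring(0, 0, 60, 120))
  expect_equal(rasterize_polygon(left, g), 1:8)
})

test_that("rasterization is monotone and exactly additive over tiling rectangles", {
  g <- pf_grid(10, 10, 30)
  set.seed(41)
  for (i in 1:20) {
    x <- sort(runif(2, -30, 330)); y <- sort(runif(2, -30, 330))
    inner <- list(rings = list(rect_ring(x[1], y[1], x[2], y[2])))
    pad <- runif(2, 0, 60)
    outer <- list(rings = list(rect_ring(x[1] - pad[1], y[1] - pad[2],
                                         x[2] + pad[1], y[2] + pad[2])))
    ci <- rasterize_polygon(inner, g); co <- rasterize_polygon(outer, g)
    expect_true(all(ci %in% co))
    # split the inner rectangle at a shared vertical edge: exact partition
    xm <- mean(x)
    a <- rasterize_polygon(list(rings = list(rect_ring(x[1], y[1], xm, y[2]))), g)
    b <- rasterize_polygon(list(rings = list(rect_ring(xm, y[1], x[2], y[2]))), g)
    expect_length(intersect(a, b), 0)
    expect_setequal(c(a, b), ci)
  }
})

test_that("point-in-polygon agrees with an independent interior-point oracle", {
  skip_if_not_installed("mgcv")
  set.seed(7)
  for (i in 1:10) {
    # random convex polygon via convex hull of random points
    pts <- matrix(runif(24, 0, 100), ncol = 2)
    hull <- pts[chull(pts), ]
    qx <- runif(200, -10, 110); qy <- runif(200, -10, 110)
    mine <- pfdisturb:::.points_in_rings(qx, qy, list(hull))
    orac <- mgcv::in.out(rbind(hull, hull[1, ]), cbind(qx, qy))
    # the edge rule may differ exactly on the boundary; random query points
    # are almost surely off it
    expect_equal(mine, as.vector(orac))
  }
})

test_that("asc raster round trip is exact for integers and close for floats", {
  g <- pf_grid(16, 16, 30, origin = c(1000, 2000))
  set.seed(5)
  year <- matrix(sample(c(0L, 1986:2020), 256, replace = TRUE), 16, 16)
  sev <- matrix(runif(256), 16, 16)
  sev[year == 0] <- NA
  forest <- matrix(runif(256) < 0.8, 16, 16)
  layers <- disturbance_layers(g, year, sev, forest)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("y.asc", "s.asc", "f.asc"))
  write_layers(layers, paths[1], paths[2], paths[3])
  back <- read_layers(paths[1], paths[2], paths[3])
  expect_identical(back$year, layers$year)
  expect_identical(back$forest, layers$forest)
  expect_equal(back$severity, layers$severity, tolerance = 1e-7)
  expect_equal(back$grid$origin, g$origin)
})

test_that("layer validation rejects out-of-range values and misregistration", {
  g <- pf_grid(4, 4, 30)
  y <- matrix(0L, 4, 4); s <- matrix(NA_real_, 4, 4); f <- matrix(TRUE, 4, 4)
  s2 <- s; s2[2, 2] <- 1.5
  y2 <- y; y2[1, 1] <- 1970L
  expect_error(disturbance_layers(g, y, s2, f), "1 severity value")
  expect_error(disturbance_layers(g, y2, s, f), "outside \\[1986, 2020\\]")
  expect_error(disturbance_layers(g, matrix(0L, 3, 4), s, f), "co-registration")
  d <- withr::local_tempdir()
  write_asc(y, file.path(d, "y.asc"), g)
  write_asc(s, file.path(d, "s.asc"), g)
  g2 <- pf_grid(4, 4, 30, origin = c(10, 0))
  write_asc(f * 1L, file.path(d, "f.asc"), g2)
  expect_error(read_layers(file.path(d, "y.asc"), file.path(d, "s.asc"),
                           file.path(d, "f.asc")), "co-registration")
})

test_that("polygon GeoJSON round trip preserves attributes and geometry", {
  polys <- list(
    pf_polygon("P1", "D1", "ROU", "Alpine", TRUE, rect_ring(0, 0, 60, 120)),
    pf_polygon("P2", "D2", "SWE", "Boreal", TRUE,
               list(rect_ring(60, 0, 120, 120), rect_ring(75, 15, 90, 30))))
  d <- withr::local_tempdir()
  p <- file.path(d, "polys.geojson")
  write_polygons(polys, p)
  back <- read_polygons(p)
  expect_length(back, 2)
  expect_equal(back[[1]]$country, "ROU")
  expect_equal(back[[2]]$in_eu, TRUE)
  g <- pf_grid(4, 4, 30)
  for (i in 1:2)
    expect_equal(rasterize_polygon(back[[i]], g),
                 rasterize_polygon(polys[[i]], g))
  expect_error(pf_polygon("P3", "D1", "", "Alpine", TRUE,
                          rect_ring(0, 0, 1, 1)), "non-null")
})

test_that("dataset table validation enforces status and mapping-year rules", {
  ok <- data.frame(dataset_id = c("D1", "D2"),
                   status = c("DOCUMENTED", "POTENTIAL"),
                   mapping_year = c(2015, NA))
  v <- validate_dataset_table(ok)
  expect_identical(v$mapping_year, c(2015L, NA_integer_))
  expect_error(validate_dataset_table(
    transform(ok, mapping_year = c(NA, NA))), "without mapping_year")
  expect_error(validate_dataset_table(
    transform(ok, mapping_year = c(1970, NA))), "outside")
  expect_error(validate_dataset_table(
    transform(ok, status = c("WILD", "POTENTIAL"))), "DOCUMENTED or POTENTIAL")
})
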