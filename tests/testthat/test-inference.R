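test_that("bootstrap CI handles degenerate inputs and is seed-reproducible", {
  spec <- boot_spec(n_iter = 2000, seed = 10)
  expect_equal(as.numeric(bootstrap_ci(c(5, 5, 5), "mean", spec)), c(5, 5))
  expect_warning(ci1 <- bootstrap_ci(7, "mean", spec), "degenerate")
  expect_equal(as.numeric(ci1), c(7, 7))
  expect_error(bootstrap_ci(numeric(0), "mean", spec), "empty")
  v <- rexp(40, 1)
  ci_a <- bootstrap_ci(v, "total", spec)
  ci_b <- bootstrap_ci(v, "total", spec)
  expect_identical(as.numeric(ci_a), as.numeric(ci_b))
  # invariance to input ordering under the same seed
  ci_c <- bootstrap_ci(rev(v), "total", spec)
  expect_identical(as.numeric(ci_a), as.numeric(ci_c))
  # point statistic inside the percentile interval
  expect_true(ci_a[1] <= attr(ci_a, "point") && attr(ci_a, "point") <= ci_a[2])
  ci_r <- bootstrap_ci(v, "rate", spec, denom = 1000)
  expect_equal(attr(ci_r, "point"), 100 * sum(v) / 1000)
  expect_error(bootstrap_ci(v, "rate", spec), "denom")
})

test_that("fixed-n and Poisson resampling differ as the theory says for totals", {
  set.seed(6)
  v <- rep(4, 100)  # constant patch size: all variability is in the count
  fix <- bootstrap_ci(v, "total", boot_spec(2000, seed = 1,
                                            count_variation = FALSE))
  poi <- bootstrap_ci(v, "total", boot_spec(2000, seed = 1))
  expect_equal(as.numeric(fix), c(400, 400))    # fixed n: degenerate
  expect_gt(poi[2] - poi[1], 50)                # Poisson: count variance shows
})

test_that("rate difference test is null-centred on identical inputs and detects separation", {
  areas <- rep(0.18, 25)
  spec <- boot_spec(n_iter = 2000, seed = 3)
  t0 <- rate_difference_test(areas, areas, 1000 * 17, 1000 * 17, spec)
  expect_equal(t0$statistic, 0)
  expect_gt(t0$p_value, 0.5)
  # all disturbance postdating: delta > 0 and p at the resolution floor
  t1 <- rate_difference_test(numeric(0), rep(0.18, 60), 1000 * 30, 1000 * 5,
                             spec)
  expect_gt(t1$statistic, 0)
  expect_equal(t1$p_value, 2 / spec$n_iter)
  expect_equal(t1$n_pre, 0)
  # degenerate window: p is NA with a warning
  expect_warning(
    t2 <- rate_difference_test(areas, areas, 1000 * 30, 0, spec),
    "degenerate")
  expect_true(is.na(t2$p_value))
})

test_that("Mann-Whitney exact p matches full enumeration and the tie convention", {
  t1 <- mann_whitney_severity_test(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1 / 3)   # 2 * (1 / C(4,2))
  expect_equal(t1$method, "exact")
  t2 <- mann_whitney_severity_test(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(t2$statistic, 2)     # n1 n2 / 2 under midranks
  expect_error(mann_whitney_severity_test(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(123)
  # exact path, no ties: match wilcox.test's exact two-sided p
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- runif(n1); y <- runif(n2)
    mine <- mann_whitney_severity_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # normal-approximation path with ties: match the tie-corrected approx
  for (i in 1:5) {
    x <- sample(seq(0, 1, 0.05), 40, replace = TRUE)
    y <- sample(seq(0, 1, 0.05), 35, replace = TRUE) + 0.02
    mine <- mann_whitney_severity_test(x, y)
    expect_equal(mine$method, "normal-approximation")
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("oversized severity samples are capped by a seeded subsample", {
  set.seed(9)
  x <- runif(1500); y <- runif(1200)
  t1 <- mann_whitney_severity_test(x, y, max_n = 1000, seed = 4)
  expect_equal(t1$n_pre, 1000)
  expect_equal(t1$n_post, 1000)
  t2 <- mann_whitney_severity_test(x, y, max_n = 1000, seed = 4)
  expect_identical(t1$p_value, t2$p_value)
  # order invariance of the seeded subsample
  t3 <- mann_whitney_severity_test(rev(x), y[order(y)], max_n = 1000, seed = 4)
  expect_identical(t1$p_value, t3$p_value)
})

test_that("significance flags follow the reporting convention", {
  expect_equal(significance_flag(c(0.04, 0.06, 0.2, NA)),
               c("**", "*", "", ""))
})

test_that("sensitivity shift 0 reproduces the baseline rates exactly", {
  sim <- fixture_sim(seed = 13)
  a <- assess_disturbance(sim$layers, sim$polygons, sim$datasets,
                          compute_ci = FALSE, compute_tests = FALSE,
                          shifts = -2:2)
  s0 <- a$sensitivity[a$sensitivity$shift == 0, ]
  ind <- a$indicators[a$indicators$status == "DOCUMENTED", ]
  for (k in seq_len(nrow(s0))) {
    base <- ind[ind$stratum_type == s0$stratum_type[k] &
                  ind$stratum == s0$stratum[k], ]
    expect_identical(s0$rate_pre[k], base$rate_pct_yr[base$period == "PRE"])
    expect_identical(s0$rate_post[k], base$rate_pct_yr[base$period == "POST"])
  }
})

test_that("an extreme negative shift empties the predating period", {
  sim <- fixture_sim(seed = 19)
  lay <- sim$layers
  # remove any disturbance in the window's first year so that, with mapping
  # years clamped to 1986, nothing at all can predate
  y <- lay$year; y[y == lay$year_min] <- 0L
  lay2 <- disturbance_layers(lay$grid, y, lay$severity, lay$forest,
                             lay$year_min, lay$year_max,
                             lay$severity_year_max)
  a <- assess_disturbance(lay2, sim$polygons, sim$datasets,
                          compute_ci = FALSE, compute_tests = FALSE,
                          shifts = c(-40, 0))
  smin <- a$sensitivity[a$sensitivity$shift == -40, ]
  expect_true(all(smin$rate_pre == 0))
  expect_true(all(smin$rate_change >= 0))
})
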