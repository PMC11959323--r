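#' Bootstrap resampling specification
#'
#' @param n_iter Number of bootstrap iterations (default 10,000, the study
#'   configuration).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Optional integer seed; every resampling call is reproducible
#'   under a fixed seed.
#' @param unit Resampling unit tag, `"patch"` (default) or `"cell"`.
#' @param count_variation If `TRUE` (default), TOTAL/RATE statistics use the
#'   Poisson bootstrap (each unit enters a resample with Poisson(1)
#'   multiplicity), so resample variance matches the compound-Poisson
#'   variance of a patch process, including the randomness of the patch
#'   count. MEAN statistics always use classical fixed-n resampling with
#'   replacement (a mean conditions on n). `FALSE` forces fixed-n resampling
#'   throughout.
#' @return List of class `boot_spec`.
#' @export
boot_spec <- function(n_iter = 10000L, level = 0.95, seed = NULL,
                      unit = c("patch", "cell"), count_variation = TRUE) {
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  structure(list(n_iter = n_iter, level = level, seed = seed,
                 unit = match.arg(unit),
                 count_variation = isTRUE(count_variation)),
            class = "boot_spec")
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# bootstrap replicate statistics for one sample; returns numeric(n_iter)
.boot_stats <- function(values, statistic, denom, n_iter, count_variation) {
  values <- sort(values)  # invariance to input ordering under a fixed seed
  n <- length(values)
  if (n == 0L) return(rep(switch(statistic, mean = NA_real_, 0), n_iter))
  fixed_n <- statistic == "mean" || !count_variation
  chunk <- max(1L, min(n_iter, floor(4e6 / max(n, 1L))))
  out <- numeric(0)
  done <- 0L
  while (done < n_iter) {
    k <- min(chunk, n_iter - done)
    if (fixed_n) {
      idx <- matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
      tot <- colSums(matrix(values[idx], nrow = n))
    } else {
      w <- matrix(stats::rpois(n * k, 1), nrow = n)
      tot <- colSums(w * values)
    }
    out <- c(out, switch(statistic,
                         mean = tot / n,
                         total = tot,
                         rate = 100 * tot / denom))
    done <- done + k
  }
  out
}

#' Bootstrap percentile confidence interval
#'
#' Percentile interval of a statistic over resamples of patch-level values.
#' For `statistic = "rate"`, the statistic is `100 * sum(values) / denom`
#' with `denom` the stratum's forest-hectare-years; `"total"` is the plain
#' sum and `"mean"` the arithmetic mean.
#'
#' @param values Patch-level quantities (areas in ha, or severities).
#' @param statistic `"mean"`, `"total"` or `"rate"`.
#' @param spec A [boot_spec()].
#' @param denom Denominator for the rate statistic (forest_ha * n_years).
#' @return Numeric `c(low, high)` with attributes `point` (the plain
#'   statistic of the input) and `spec`.
#' @export
bootstrap_ci <- function(values, statistic = c("mean", "total", "rate"),
                         spec = boot_spec(), denom = NULL) {
  statistic <- match.arg(statistic)
  if (length(values) == 0L) stop("empty input to bootstrap_ci", call. = FALSE)
  if (statistic == "rate" && (is.null(denom) || is.na(denom) || denom <= 0))
    stop("rate statistic needs a positive denom", call. = FALSE)
  point <- switch(statistic, mean = mean(values), total = sum(values),
                  rate = 100 * sum(values) / denom)
  if (length(values) == 1L && (statistic == "mean" || !spec$count_variation)) {
    warning("bootstrap_ci: single value, interval is degenerate", call. = FALSE)
    ci <- c(point, point)
  } else {
    stats_v <- .with_seed(spec$seed,
      .boot_stats(values, statistic, denom %||% 1, spec$n_iter,
                  spec$count_variation))
    a <- (1 - spec$level) / 2
    ci <- unname(stats::quantile(stats_v, c(a, 1 - a), type = 7))
  }
  attr(ci, "point") <- point
  attr(ci, "spec") <- spec
  ci
}

#' Bootstrap test for a difference in mean annual disturbance rates
#'
#' Resamples the predating and postdating patch sets independently and forms
#' the bootstrap distribution of the rate difference
#' `delta = rate_post - rate_pre`. The two-sided p-value is
#' `2 * min(share of resampled delta <= 0, share >= 0)`, clipped to
#' `[2/n_iter, 1]` (the resolution floor of a bootstrap p-value).
#'
#' @param pre_areas,post_areas Patch disturbed areas (ha) in each period.
#' @param denom_pre,denom_post Forest-hectare-years denominators
#'   (`forest_ha * n_years`, pooled over polygons for aggregated strata).
#' @param spec A [boot_spec()].
#' @return List of class `pf_test` with kind `"RATE_DIFF"`, `statistic`
#'   (the observed rate change), `p_value` (NA with a warning when a period
#'   has no patches or no window), `n_pre`, `n_post`, `rate_pre`,
#'   `rate_post`, `spec`.
#' @export
rate_difference_test <- function(pre_areas, post_areas, denom_pre, denom_post,
                                 spec = boot_spec()) {
  ok_pre <- !is.na(denom_pre) && denom_pre > 0
  ok_post <- !is.na(denom_post) && denom_post > 0
  rate_pre <- if (ok_pre) 100 * sum(pre_areas) / denom_pre else NA_real_
  rate_post <- if (ok_post) 100 * sum(post_areas) / denom_post else NA_real_
  delta <- rate_post - rate_pre
  p <- NA_real_
  if (!ok_pre || !ok_post ||
      (length(pre_areas) == 0L && length(post_areas) == 0L)) {
    # no window, or no patches at all: the difference is still reported but
    # carries no resampling distribution
    warning("rate_difference_test: degenerate periods; p = NA", call. = FALSE)
  } else {
    d <- .with_seed(spec$seed, {
      rp <- .boot_stats(pre_areas, "rate", denom_pre, spec$n_iter,
                        spec$count_variation)
      ro <- .boot_stats(post_areas, "rate", denom_post, spec$n_iter,
                        spec$count_variation)
      ro - rp
    })
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    p <- min(max(p, 2 / spec$n_iter), 1)
  }
  structure(list(kind = "RATE_DIFF", statistic = delta, p_value = p,
                 n_pre = length(pre_areas), n_post = length(post_areas),
                 rate_pre = rate_pre, rate_post = rate_post, spec = spec),
            class = "pf_test")
}

# exact null distribution of the rank sum via dynamic programming over the
# doubled midranks (identical to full enumeration of the C(N, n1) subsets,
# feasible at the n1*n2 <= 400 bound where enumeration is not)
.exact_ranksum_p <- function(r2, n1, w2_obs) {
  N <- length(r2)
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # dp[k+1, s+1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)
  dp[1L, 1L] <- 1
  for (d in r2) {
    kmax <- n1
    for (k in kmax:1) {
      src <- dp[k, 1:(maxs + 1L - d)]
      if (any(src != 0)) dp[k + 1L, (d + 1L):(maxs + 1L)] <-
          dp[k + 1L, (d + 1L):(maxs + 1L)] + src
    }
  }
  counts <- dp[n1 + 1L, ]
  tot <- sum(counts)
  sums <- 0:maxs
  p_le <- sum(counts[sums <= w2_obs]) / tot
  p_ge <- sum(counts[sums >= w2_obs]) / tot
  min(2 * min(p_le, p_ge), 1)
}

#' Mann-Whitney U test for patch severities, with subsampling cap
#'
#' Compares the patch mean severities of the predating and postdating periods
#' with the rank-sum U statistic under midrank tie handling. Groups larger
#' than `max_n` are first reduced to a seeded uniform random subsample without
#' replacement (a cheap guard against spatial autocorrelation inflating the
#' effective sample size). The two-sided p-value is exact (full enumeration of
#' the null rank distribution, computed by dynamic programming) when
#' `n1 * n2 <= 400`, otherwise a normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Severity samples (predating / postdating patch means).
#' @param max_n Subsampling cap per group (default 1000).
#' @param seed Optional seed for the subsample.
#' @param exact_threshold Use the exact distribution when `n1 * n2` is at or
#'   below this product.
#' @return List of class `pf_test` with kind `"SEVERITY_MW"`, `statistic`
#'   (U for the first sample), `p_value`, `n_pre`, `n_post`, `method`.
#' @export
mann_whitney_severity_test <- function(x, y, max_n = 1000L, seed = NULL,
                                       exact_threshold = 400L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("mann_whitney_severity_test: both groups must be non-empty",
         call. = FALSE)
  x <- sort(x); y <- sort(y)  # order invariance of the seeded subsample
  .with_seed(seed, {
    if (length(x) > max_n) x <- sample(x, max_n)
    if (length(y) > max_n) y <- sample(y, max_n)
  })
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= exact_threshold) {
    r2 <- as.integer(round(2 * r))
    w2_obs <- as.integer(round(2 * sum(r[seq_len(n1)])))
    p <- .exact_ranksum_p(r2, n1, w2_obs)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(2 * stats::pnorm(-z), 1)
    method <- "normal-approximation"
  }
  structure(list(kind = "SEVERITY_MW", statistic = U, p_value = p,
                 n_pre = n1, n_post = n2, method = method, max_n = max_n),
            class = "pf_test")
}

#' @export
print.pf_test <- function(x, ...) {
  cat(sprintf("<pf_test %s> statistic = %.4g, p = %s (n_pre = %d, n_post = %d)%s\n",
              x$kind, x$statistic,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value),
              x$n_pre, x$n_post, significance_flag(x$p_value)))
  invisible(x)
}

#' Significance flag convention
#'
#' `"**"` for p < 0.05, `"*"` for p < 0.10, empty otherwise.
#'
#' @param p p-value (NA allowed).
#' @return Character flag.
#' @export
significance_flag <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}
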