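#' Mean severity of a single patch
#'
#' The arithmetic mean of the disturbance severity of all cells on the patch.
#' Severity is defined only for disturbance years up to the severity product's
#' last year (2016 by default); a patch containing any NODATA cell is flagged
#' and excluded from severity summaries.
#'
#' @param cells Integer vector of the patch's linear cell indices.
#' @param severity Severity matrix (NA = NODATA).
#' @return The mean, or `NA` if any cell is NODATA.
#' @export
patch_mean_severity <- function(cells, severity) {
  sv <- severity[cells]
  if (anyNA(sv)) return(NA_real_)
  mean(sv)
}

#' Stratum-level mean of patch mean severities
#'
#' The unweighted mean over patches: a 1-cell patch counts exactly as much as
#' a 100-cell patch. This is the patch-level aggregation of the severity
#' indicator (cell-weighted means differ whenever patch size correlates with
#' severity).
#'
#' @param patch_means Numeric vector of patch mean severities (NA entries,
#'   i.e. flagged patches, are dropped with a count kept in the result).
#' @return List with `mean` (NA if no eligible patch), `n_patches`,
#'   `n_excluded`.
#' @export
stratum_mean_severity <- function(patch_means) {
  n_excl <- sum(is.na(patch_means))
  v <- patch_means[!is.na(patch_means)]
  list(mean = if (length(v)) mean(v) else NA_real_,
       n_patches = length(v), n_excluded = n_excl)
}

#' Change in mean severity between periods
#'
#' @param mean_pre,mean_post Stratum mean severities.
#' @return `mean_post - mean_pre`.
#' @export
severity_change <- function(mean_pre, mean_post) mean_post - mean_pre
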