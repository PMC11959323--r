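#' Bundled reference indicator tables for European primary forests
#'
#' Published continental assessment values (areas in thousand ha, mean annual
#' disturbance rates in %/yr, patch severities in 0-1) for documented primary
#' forest (`"pf"`: predating/postdating indicators by biogeographical region,
#' with EU and Europe totals), potential primary forest (`"ppf"`: full-window
#' 1986-2020 indicators) and headline hectare figures (`"headline"`). Bundled
#' for arithmetic consistency checks - recomputing proportions, rate changes,
#' severity changes and combined extents from the printed values - not as
#' model input.
#'
#' @param which `"pf"`, `"ppf"` or `"headline"`.
#' @return data.frame.
#' @export
reference_table <- function(which = c("pf", "ppf", "headline")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   switch(which,
                          pf = "reference_pf_indicators.csv",
                          ppf = "reference_ppf_indicators.csv",
                          headline = "reference_headline.csv"),
                   package = "pfdisturb", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
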