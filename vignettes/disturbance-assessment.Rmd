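---
title: "Assessing disturbance in primary forests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing disturbance in primary forests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfdisturb)
```

## The estimand

A primary-forest polygon inventory certifies, for each dataset, that at its
*mapping year* the mapped stands showed no visible sign of human use. Any
disturbance mapped at or before that year must therefore have been part of
the natural disturbance regime; disturbances after it may be natural or
anthropogenic. The package estimates, for documented primary forests,

* the area disturbed in the predating window (`year_min` … mapping year,
  inclusive) and postdating window (mapping year + 1 … `year_max`),
* the proportion of forest area disturbed, `100 · A_dist / A_forest`, and
* the mean annual rate of area disturbed,
  `100 · A_dist / (A_forest · n_years)`,

and tests whether the rate changed between the two periods. The rate is the
primary indicator: with a mapping year late in the window (the area-weighted
mean mapping year of the European inventory is 2015 in a 1986–2020 window),
the predating window is about six times longer than the postdating one, and
raw disturbed areas are not comparable across periods. Potential primary
forests carry no mapping year, so their indicators are computed over the
full window only.

The predating rate estimates the *surviving* natural background rate, not
the full one: stands anthropogenically disturbed before mapping were never
mapped as primary. The generator's selection-bias mode (an extra labeled
hazard stream that removes affected candidate polygons from the documented
layer) reproduces this lower-bound property, and a test demonstrates it.

## Data model and geometry

All computation happens on a planar equal-area grid of square cells
(default 30 m, 0.09 ha). Three co-registered rasters form the input: the
disturbance year (integer; 0 = undisturbed), the disturbance severity
(0–1 fraction of canopy lost, available only through `severity_year_max`,
default 2016), and a binary forest mask. On-disk exchange uses single-band
ESRI ASCII grids and GeoJSON polygons; the package validates ranges and
co-registration on read and reports offending counts.

Polygons are rasterized by the cell-center rule with half-open edges:
a center on a polygon's bottom or left boundary is inside, on the top or
right outside. This makes rasterization deterministic and exactly additive
for polygons that tile space — two polygons sharing an edge never both claim
a cell — which the indicator arithmetic relies on. Polygons carry one
country/bioregion/EU attribute each; geometries spanning two countries must
be split upstream. Where documented and potential polygons overlap, the
documented layer wins and potential cells are clipped away (the two statuses
are otherwise assessed separately throughout).

## Patches and the minimum mapping unit

Disturbance patches are maximal rook-connected (4-neighbor) components of
cells sharing the same disturbance year; cells of different years never join
(the source product is annual, and severity is defined per patch per year).
Patches smaller than the MMU — 2 cells by default, the hectare value
(0.18 ha at 30 m) being derived from the grid so non-30-m grids behave
sensibly — are removed, as are forest-mask components below the MMU. The
MMU bound is inclusive: a 2-cell patch is the smallest retained unit.
Disturbed cells are counted only where they intersect both the polygon and
the MMU-filtered forest mask, because the denominator is mask-based.

Internally all areas are carried as integer cell counts and converted to
hectares once at the end; additivity identities (predating + postdating =
full window per polygon; country sums = continental totals) therefore hold
exactly, not merely to rounding.

## Aggregation

Indicators are aggregated at country, biogeographical region (with the
Alpine region pre-split into its Scandinavian and southern subregions as an
input attribute), EU and continental level. Areas sum; proportions and rates
are recomputed from the pooled sums, never averaged across datasets, so
rates are invariant to splitting a stratum into sub-polygons. Because
datasets have different mapping years, the pooled rate uses a
forest-hectare-years denominator, `100 · Σ A_dist / Σ (A_forest · n_years)`,
which reduces to the plain rate when all member polygons share one mapping
year and keeps additivity.

Severity is patch-level: a patch's severity is the mean over **all** its
cells; a stratum's severity is the unweighted mean over patches (a 1-cell
patch counts as much as a 100-cell one, matching the patch-level
definition). A patch belongs to a polygon's stratum if any of its cells
lies inside the polygon; it is counted once per stratum, and when polygons
of different datasets touch one patch its period is attributed via the
polygon with the largest overlap (ties broken by lowest polygon id).
Patches later than `severity_year_max`, or containing severity NODATA
cells, are excluded from severity summaries and counted in `n_excluded`.

## Uncertainty and tests

Confidence intervals are bootstrap percentile intervals (default 10,000
iterations, 95%), with the patch as the resampling unit. For **means**
(severity) the classical fixed-n resample with replacement is used:
a mean conditions on the number of patches. For **totals and rates** the
package uses the Poisson bootstrap — each patch enters a resample with
Poisson(1) multiplicity — because a disturbed-area total is a statistic of
a point process: both the sizes *and the number* of patches are random.
A fixed-n resample of patch areas conditions away the count variation and
its intervals undercover badly (for geometric-like patch sizes by roughly
a factor two in standard-error terms); the Poisson bootstrap's resample
variance matches the compound-process variance. The fixed-n behaviour
remains available via `boot_spec(count_variation = FALSE)`.

The rate-difference test resamples the predating and postdating patch sets
independently and computes the two-sided p-value
`2 · min(P(Δ* ≤ 0), P(Δ* ≥ 0))`, clipped to `[2/n_iter, 1]`. A period with
no patches resamples as a constant zero rate; p is undefined only when both
periods are empty or a window is missing (mapping year at the window end).

The severity comparison is a Mann–Whitney U test with midrank ties. Groups
above 1000 patches are first reduced by a seeded uniform random subsample —
a cheap guard against spatially autocorrelated patches inflating the
effective sample size (an optional distance-thinning rule was considered
and rejected as it requires a spatial correlation model the data cannot
support). The null distribution is exact when `n1 · n2 ≤ 400`, computed by
dynamic programming over the doubled midranks (identical to enumerating all
rank assignments, but feasible); otherwise a normal approximation with
tie-corrected variance and continuity correction is used. Significance is
flagged `*` for p < 0.10 and `**` for p < 0.05; no multiple-testing
correction is applied across strata.

All resampling is reproducible under a fixed seed and invariant to the
input ordering of patches (values are sorted before resampling).

The sensitivity analysis shifts every dataset's mapping year by −3…+3 years
(clamped to the window) and recomputes the per-stratum rates; shift 0 goes
through literally the same arithmetic as the baseline and reproduces it
bit-for-bit.

## The synthetic landscape generator

The generator emulates the statistical structure the assessment assumes,
with known ground truth, and writes the exact formats the package reads:

* Bernoulli forest mask (default cover 0.7 — at that density the mask is
  essentially one connected component, so MMU filtering of the mask removes
  almost nothing).
* Rectangular polygon blocks tiling the grid, assigned round-robin to
  datasets with country/bioregion/EU attributes and mapping years
  (defaults 2013/2015/2017: area-weighted mean ≈ 2015, the continental
  inventory's weighted mean mapping year).
* Each year, patch seeds appear in undisturbed forest cells with
  probability `hazard / mean_patch_cells`, where `hazard` switches from
  `hazard_pre` to `hazard_post` after the cell's dataset mapping year
  (defaults 0.0008 and 0.0015, echoing continental rates of 0.08 and
  0.15 %/yr). Seeds grow by random rook-frontier accretion to a target size
  of `2 + Geometric` cells with mean `mean_patch_cells` (default 4). The
  floor of 2 cells equals the default MMU: a generator emitting sub-MMU
  patches would make its own truth rates unrecoverable by construction,
  since the MMU filter removes part of the generated area. With this
  parameterization the per-cell annual disturbance probability is `hazard`
  and the expected disturbed fraction after `Y` years is
  `1 − (1 − hazard)^Y`, which the tests check in closed form.
* Cells are disturbed at most once (first year wins), mirroring the
  single-year-per-cell source product. A corollary worth knowing when
  designing null experiments: at high hazards the susceptible forest
  depletes over time, so the realized late-window rate drifts slightly
  below the early-window rate even under equal hazards (an O(hazard²)
  effect). Calibration experiments therefore use low hazards where the
  drift is negligible against sampling noise.
* Patch severity is Beta(6.7, 3.3) (mean 0.67, the continental mean patch
  severity) plus cell-level Gaussian jitter (sd 0.05), clipped to [0, 1],
  assigned only for years within the severity window.

What the generator does **not** emulate: topography and climate forcing,
agent identity (fire/wind/bark beetle), spatially correlated hazards,
multi-year disturbance episodes, mapping-year error, and geometric
misregistration between layers. Passing recovery tests therefore validate
the estimator arithmetic and its uncertainty statements under the assumed
sampling structure — they do not certify the upstream remote-sensing maps.

## Problem sizes and numerical choices

The validation suite uses 256×256 grids with 100 replicate seeds and 1,000
bootstrap iterations for rate-recovery and CI-coverage checks, 500
replicates at 64×64 with 500 iterations for null calibration of both tests,
and 200 random ≤32×32 rasters against a brute-force flood-fill oracle for
patch labeling — sizes chosen to put Monte Carlo error well below the
property margins being asserted while keeping the default test run fast.
Degenerate inputs are defined, not exceptional: zero forest area yields NA
proportions; a mapping year at the window end yields NA postdating rates;
single-value bootstrap inputs yield degenerate intervals with a warning;
empty polygon layers yield empty output tables.

## Known limitations

* Attribution is period-level only: no individual postdating disturbance
  can be labeled natural or anthropogenic, and the predating rate is a
  lower bound on the full natural + anthropogenic background (selection
  bias).
* The grid is assumed planar equal-area; reprojection is out of scope and
  a geographic-looking CRS tag only triggers a warning.
* The subsampling guard in the severity test randomizes rather than models
  spatial autocorrelation.
* Country-level comparisons against reported areas are screening output:
  forest definitions behind the mask and behind reported statistics differ.
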