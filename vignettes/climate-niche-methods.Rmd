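---
title: "Quantifying tick climate niches from occurrence records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tick climate niches from occurrence records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickniche)
library(dplyr)
```

tickniche quantifies and compares the *realized climate niches* of tick
species (or any georeferenced taxon) from compiled occurrence records. A
record set is curated, loaded with monthly environmental covariates,
projected into a reduced climate space, and summarized as kernel-smoothed
occupancy densities whose pairwise overlap is measured with Schoener's D
and tested by permutation. This vignette explains the model behind each
stage, the tunable parameters and their defaults, and the design decisions
taken where the methodology is genuinely open.

## Record curation

Occurrence compilations mix reliable, precisely georeferenced captures with
records that name only a genus, a province, or an ambiguous locality. The
curation model is deliberately simple: each record carries a
`locality_quality` flag (`coordinates`, `unambiguous_name`,
`admin_division`, `ambiguous_name`, `genus_only`) and only the first two
levels survive `filter_records()`. Geography is a closed rectangular
window — the default is the western Palearctic box 11°W–45°E, 29°N–71°N —
with *region tags* overriding pure geometry: a tag on the
inclusion-exception list (default: Canary Islands) keeps a record that
falls outside the box, and a tag on the exclusion list (default: Iceland,
Azores) drops one inside it. Tags rather than island polygons drive these
exceptions because the box itself cannot express them: the Canaries lie
south of the box yet belong to the surveyed territory. Records without a
collection year or day are retained — temporal metadata never gates
inclusion, since most compiled records lack it.

Every rejection is tallied under the first rule the record violates
(`missing_coordinates`, `genus_only`, `admin_division`, `ambiguous_name`,
`unaccepted_name`, `excluded_region`, `outside_window`); rejected plus
retained always equals the input count, and filtering is idempotent.

Species names are harmonized before filtering. The built-in tables
collapse *Rhipicephalus sanguineus* and the morphologically confusable
*R. turanicus* into a single *R. sanguineus* group label — species-level
identifications inside that complex are widely considered unreliable — and
map *Hyalomma detritum* to its senior synonym *Hy. scupense*. The raw name
is preserved in `species_raw` for audit, and names resolving to neither an
accepted binomial nor a group label are flagged, never silently passed
through.

Percentages in `summarize_counts()` and `host_crosstab()` are rounded half
up to one decimal, the convention of printed occurrence tables; hexagon
cell percentages are reported at full precision because they feed maps,
not tables.

## Environmental covariates

Monthly covariate grids (LST, NDVI, optionally rainfall and min/max
temperature) are read from a plain-text raster dialect — the ESRI
ASCII-grid layout with an `xllcenter`/`yllcenter` header — chosen so the
package needs no geospatial stack and fixtures remain human-readable.
Values are point-registered at cell centers. `attach_environment()` gives
each record the value of the nearest cell center, computed in planar
degrees: at the ~5-km cells of satellite monthly products, and within a
mid-latitude window, the difference between planar and great-circle
nearest centers is negligible relative to cell size, and the choice keeps
the operation exactly invertible and testable against a brute-force scan.
Ties (a point exactly between centers) go to the lower row/column index,
i.e. south and west — an arbitrary but fixed convention. No value is ever
interpolated or fabricated: points outside the outer cell edges are
flagged, and a record touching any nodata layer is marked incomplete and
excluded from climate-space fitting by default.

## The reduced climate space

The 24 monthly LST and NDVI values per cell are reduced by PCA. Because
temperature (°C or K) and NDVI (dimensionless, ~0–1) are incommensurable,
the decomposition is of the **correlation** matrix: every column is
standardized before the eigendecomposition. Three axes are retained by
default (two supported for plotting). The PCA is fitted on the
*background* — all valid cells of the territory — and records are then
projected into it; fitting on the environment rather than on occurrences
makes the space species-independent, so every species is measured in the
same coordinates and availability is well defined.

PCA axis signs are arbitrary. Each axis is oriented so its
largest-magnitude loading is positive, which makes runs reproducible
across linear-algebra backends; `interpret_axes()` reports signed Pearson
correlations of each axis with interpretable annual summaries (per-variable
annual mean and annual range), but only the magnitudes are meaningful
invariants. On monthly temperature/greenness data the leading axes
typically track mean annual temperature, seasonal temperature amplitude,
and mean greenness.

## Occupancy densities and Schoener's D

Overlap is computed in the climate space, not in geography, following the
kernel-density framework for niche comparison:

1. **Grid.** `make_grid()` divides each retained axis into `r` equal bins
   (default `r = 100`) spanning the pooled background and occurrence
   scores, expanded by a 5 % margin so kernel mass at the data edge is not
   clipped. Bins are half-open `[low, high)` with the last bin closed;
   a point on an interior edge belongs to the higher bin.
2. **Densities.** The occurrence density `o` and the availability density
   `e` (from the background scores) are product-Gaussian kernel mixtures
   evaluated *exactly* at cell centers and normalized to sum to 1.
   Bandwidths default to Silverman's rule of thumb per axis
   (`stats::bw.nrd0`) times a configurable multiplier.
3. **Occupancy.** With availability correction on (the default),
   `z ∝ o/e` on cells whose availability exceeds a floor of 1e-12 of
   total mass and 0 elsewhere, renormalized; cells below the floor are
   treated as uninhabitable. The correction can be switched off, giving
   `z = o`, which is appropriate when comparing samples drawn directly in
   score space with uniform availability.
4. **Overlap.** Schoener's D between two occupancies,
   `D = 1 − ½ Σ |z₁ − z₂|`, symmetric and bounded in [0, 1].

The default dimensionality is `d = 2`: the dominant structure of monthly
climate PCAs lives on the first two axes, 2-D grids plot directly, and the
cost of densities scales as `r^d`. Three-dimensional grids are fully
supported (`d = 3`) for analyses that retain the third axis.

## The equivalency test

`equivalency_test()` asks whether two species' occurrences are
interchangeable in climate space. The observed D comes from the full
density pipeline; under the null, the pooled occurrence scores are
repartitioned at random (without replacement) into groups of the original
sizes and the *entire* pipeline — Silverman bandwidths included — is
recomputed per replicate, so the null distribution reflects every
data-dependent choice the observed statistic made. The p-value is
one-sided on the lower tail with the add-one convention,
`p = (1 + #{D_null ≤ D_obs}) / (N + 1)`; with the default `N = 99` the
smallest attainable p is 0.01. Equivalency is *rejected* when the observed
niches are less similar than random reallocation produces. The grid is
built once from the pooled data and held fixed across replicates — the
hypothesis concerns the allocation of points, not the support of the
space.

Because the null really is exchangeable under random reallocation, the
test is exactly calibrated by construction; the test suite verifies this
empirically (type-I error at the nominal 5 % level, p-value uniformity)
rather than assuming it.

## Habitat classification

`kmeans_classify()` groups territory cells by their 24-value seasonal
profile. Features are standardized per (variable, month) column —
otherwise temperature would dominate NDVI purely through units; whether to
standardize is a genuine choice, and it is this package's, documented
rather than inherited. Clustering is Lloyd's algorithm under the Euclidean
metric with k-means++ initialization, up to 300 iterations, a relative
objective tolerance of 1e-6, and the best of `n_restarts` (default 10)
restarts by within-cluster sum of squares. A cluster that empties is
reseeded at the point farthest from its centroid. There is no defensible
universal `k` for seasonal climate classes, so `k` has no default in
spirit: choose it per territory (the per-category seasonal signatures from
`category_stats()` are the tool for judging a choice). Label *identities*
are arbitrary across seeds; only the partition is meaningful, and tests
compare partitions with the adjusted Rand index.

## Hexagonal geographic summaries

`hex_percentages()` aggregates records into pointy-top hexagons addressed
by axial coordinates, with "0.5° resolution" interpreted as the horizontal
center-to-center spacing between adjacent columns (the natural reading for
a display grid; the geometry is otherwise underdetermined). Assignment
uses fractional axial coordinates and cube rounding, which resolves
edge-equidistant points deterministically. Longitude/latitude are treated
as planar, a cartographic approximation adequate for display-scale
summaries and stated as such.

## The synthetic generator

Real compilations and decade-scale satellite composites cannot ship with a
package, so every stage is validated against `simulate_raster_stack()` and
`simulate_occurrences()`, which generate data with *known* structure:

- **Fields.** Each variable's monthly layer is a linear spatial mean
  surface plus a sinusoid `amplitude · cos(2π(m − phase)/12)` (amplitude
  itself a linear surface) plus Gaussian noise. The defaults sketch the
  western Palearctic at desk scale: a 55 × 41 one-degree grid whose cell
  edges span 11°W–44°E / 29°N–70°N — nested inside the study window so
  that coordinate jitter within edge cells cannot leak outside it — with
  LST warm in the south, peaking in July, more seasonal in the north
  (base 25 °C, −0.45 °C per degree northward, amplitude 8 °C, noise
  1 °C), and NDVI greener northward with a late-spring peak (base 0.45,
  amplitude 0.15, noise 0.02).
- **Occurrences.** A species is a Gaussian niche in named environmental
  variables; cells are sampled with probability proportional to the niche
  density at the cell's environment (computed on the log scale so sharply
  peaked niches do not underflow), times an optional spatial bias field,
  and coordinates are jittered uniformly within the source cell. Host
  names, stages and curation defects are injected at configured rates with
  *exact* counts on disjoint row sets, recorded in a truth ledger — so
  filter tests can demand exact recovery, not approximate agreement.
- **Known overlap.** Niches can also be specified directly on
  climate-space axes (`simulate_niche_scores()`), where
  `gaussian_overlap_d()` integrates the two generating densities
  numerically on the analysis grid — an oracle the kernel pipeline's
  estimate is checked against (within ±0.05 at n = 2,000 per species,
  r = 100, d = 2, across low/medium/high-overlap configurations).

What the generator does **not** emulate: spatial autocorrelation of
sampling effort beyond a user-supplied bias matrix, literature-driven
reporting bias, temporal trends or phenology, misidentification error, and
coastline/nodata geometry. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under controlled conditions, not
that any real compilation is unbiased — on real data the availability
correction and the equivalency test inherit whatever sampling bias the
records carry.

## Numerical choices and degenerate inputs

- Percent rounding is half *up* (away from zero) to one decimal; base R's
  banker's rounding would disagree on exact halves.
- Kernel densities are renormalized over the grid, so mass outside the
  gridded range (bounded by the 5 % margin) is redistributed rather than
  lost; D is computed between renormalized surfaces.
- The availability floor (1e-12 of total mass) prevents division blow-ups
  on numerically empty cells; an availability surface entirely below the
  floor is an error, as is an occurrence density with no mass on habitable
  cells.
- A constant covariate column is a named error in `fit_climate_space()`
  (a correlation PCA is undefined there); constant features in k-means are
  given unit scale and simply carry no information.
- Degenerate grid axes (min = max), zero bandwidths, and sub-minimal
  occurrence counts (`< 5` per species for the permutation test, `< 19`
  permutations) are explicit errors naming the offender.
- All stochastic steps (simulation, k-means restarts, permutations) take
  explicit integer seeds and are bit-reproducible; nothing reads global
  RNG state without restoring it.

## Problem sizes used in the shipped checks

The validation suite exercises the pipeline at sizes chosen to make every
statistical property measurable while remaining comfortable on a single
CPU: oracle comparisons on grids up to 20³, calibration of the
equivalency test with 200 repetitions of N = 99 permutations at n = 30
points per sample, overlap recovery at n = 2,000 points per species on a
100 × 100 grid, and k-means recovery on 10 × 12-cell territories across
10 seeds. These are the package's reference conditions; larger analyses
scale linearly in points and as `r^d` in the grid.

## Known limitations

- Planar-degree distances (cell lookup, hexagons) are display-scale
  approximations; no equal-area or great-circle support.
- GeoTIFF and other binary raster formats are not read; convert to the
  ASCII dialect first.
- The availability correction conditions on the background of the whole
  window; niche comparisons across *different* windows are out of scope,
  as are niche similarity (background randomization) tests and the
  Hellinger-based I statistic.
- `k` selection for habitat classes is deliberately manual.
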