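---
title: "Delimiting areas of endemism by geographic interpolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting areas of endemism by geographic interpolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An area of endemism is a region delimited by the overlapping ranges of two or
more species restricted to it — the basic unit of historical biogeography and
a common currency for conservation prioritization. The classical way to find
such areas is to overlay a grid on the study region, score each cell for the
species it contains, and run a grid-based optimality or parsimony analysis.
Grid methods inherit a Boolean artifact: a single record placed anywhere in a
cell "fills" the whole cell, two records in opposite corners of one cell count
as complete overlap, and the delimited areas snap to cell boundaries at
whatever resolution was chosen.

Geographic Interpolation of Endemism (GIE) removes the grid from the inference
itself. Each species' range is summarized by the centroid of its occurrence
records and interpolated as a smooth, circular *area of influence*; the
cell-wise sum of influences — the kernel index — measures range overlap
continuously, and areas of endemism fall out as connected regions above an
isoline of the consensus surface, with fuzzy edges and a natural hierarchy of
nested areas across spatial scales. A raster appears only at the very end, for
display and delimitation, and its resolution is a rendering choice rather than
an analytical one.

## The procedure

`gie_run()` chains five steps, each exposed as its own function:

1. **Centroid** (`compute_centroid()`): the plain arithmetic mean of each
   species' record longitudes and latitudes. No geodesic averaging is done —
   at the continental scales the method targets the difference is negligible,
   and the plain mean is the method's definition. Species spanning more than
   180° of longitude trigger a warning.
2. **Range distance** (`max_range_distance()`): the great-circle distance from
   the centroid to the species' farthest record, in km, zero for singletons.
3. **Categorization** (`assign_category()`): species are sorted into
   range-size classes by that distance. All species in a class share one
   influence radius — the class upper bound — so that restricted species are
   interpolated at a fine scale and widespread species at a coarse one.
4. **Kernel interpolation** (`rasterize_category()`): each species contributes
   `exp(-d² / 2σ²)` at distance `d` from its centroid, truncated to exactly 0
   beyond the class radius `r`, with `σ = r / 3`. The kernel index `k` of a
   cell is the sum of these influences over the class's species.
5. **Consensus and delimitation** (`build_consensus()`, `extract_isolines()`,
   `delimit_areas()`): each class surface is min–max standardized to [0, 1],
   the consensus is their (optionally weighted) sum, and areas of endemism are
   the connected components above a chosen level, each supported by the
   species whose records fall entirely inside it (its *synendemic* species).

## Parameters that matter

* **Category scheme** (`category_scheme()`, `scheme_preset()`). Breakpoints in
  km; the default nine-class scheme is 50, 200, 400, 600, 800, 1000, 1500,
  2000, 3299 km, with a coarser five-class and a finer eighteen-class preset
  for sensitivity analysis. Class intervals are right-closed — "up to 50 km"
  means [0, 50], the next class (50, 200] — so a species sitting exactly on a
  boundary keeps the smaller radius. The continuous distance makes the choice
  at the boundary arbitrary in principle; we resolve it conservatively because
  assigning the larger radius would overestimate the range of the more
  restricted species, which is the direction of error the method most needs to
  avoid. A distance beyond the last breakpoint is an error (extend the
  scheme), not a silent clamp.
* **Kernel width ratio** (`sigma_ratio`, default 3). The Gaussian is
  parameterized so the influence has essentially vanished (3σ, `exp(-4.5)` ≈
  0.011) at the circular boundary, honoring both the Gaussian decay and the
  literal circular area of influence; the truncation makes the circle exact.
  The ratio is configurable; smaller values fatten the kernel tails, larger
  values sharpen the peak.
* **The kernel index is a raw sum**, not a density: no normalization by
  bandwidth area or species count is applied. Any global per-category scale
  factor is absorbed by the min–max standardization before the consensus, an
  invariance the test suite checks cell-by-cell, so the choice cannot affect
  the delimited areas.
* **Grid** (`grid_spec()`, default cell 0.1°). A plain WGS84 lon/lat lattice;
  the default extent covers all centroids padded by the largest influence
  radius. Cell-to-centroid distances are haversine on a sphere of mean radius
  6371.0088 km — the same metric used for range distances — so no projection
  machinery is needed at continental scale.
* **Delimitation level** (`level`, default 0.05 of the consensus maximum).
  The outer, fuzziest boundary. There is no canonical threshold: operational
  areas are a matter of spatial scale, so the intended use is an ascending
  ladder of isolines (`extract_isolines()`, or `delimit_areas()` at several
  levels), which yields nested areas — smaller, better-supported areas inside
  more inclusive ones. All outputs record the absolute level used.
* **Attribution rule** (`q`, default 1). A species supports an area only if
  *all* its records fall inside — the strictest reading of synendemism. A
  relaxed fraction (`q = 0.5`: at least half the records) is available for
  exploratory work; with `q < 1` a species may support several areas.

## Numerical choices

Distances use the haversine formula (via geosphere) on the IUGG mean-radius
sphere; the method's sources report range sizes in km without naming a metric,
and haversine agrees with geodesic distances to well under the width of a
raster cell at these scales. Per-cell kernel evaluation skips species whose
centroid lies beyond the truncation radius plus one cell diagonal — a pure
optimization that is exactly equivalent to the full scan because the kernel is
identically zero there; the test suite compares it against a brute-force
double loop at 1e-9 relative tolerance. Isolines come from marching squares
(`grDevices::contourLines`) with linear sub-cell interpolation; connected
components use 4-connectivity with cells exactly at the level counted inside;
components are labelled west-to-east so area identifiers are deterministic.
Records are assigned to cells half-open in both axes ([west, east) × [south,
north)), the same convention as the presence/absence grid matrix, so a record
on a shared edge belongs to exactly one cell; records exactly on the grid's
outer north/east boundary are kept in the outermost cell. A constant surface
standardizes to all zeros rather than NaN. Areas touching the grid border are
flagged as possibly truncated rather than dropped.

## Diagnostics

* **Rarefaction** (`rarefy_centroids()`): removes 10, 20 and 30% of each
  species' records at random (100 randomizations by default) and reports the
  mean and variance of the centroid displacement in km. The removal count is
  `round(f · n)` floored at 1; single-record species are skipped, since
  removing their only record is undefined. Removal is per-species by default;
  a `"global"` mode removes the fraction from the pooled table instead, for
  the reading under which whole-database sampling effort is being probed.
* **Elongation** (`elongation_index()`): the circular area of influence
  over-generalizes elongated ranges (rivers, mountain chains). The index is
  the aspect ratio of the dispersion ellipse — the square root of the
  eigenvalue ratio of the record covariance in a local km projection — 1 for
  isotropic scatter, flagged at 3 by default; collinear and two-record sets
  have a degenerate minor axis and are capped at a sentinel (100) and flagged.
* **Disjunction** (`detect_disjoint()`): single-linkage clustering of records
  at a km gap threshold. Disjoint species can be split into per-cluster
  pseudo-species (`split = TRUE`) so each cluster gets its own centroid and
  radius and the species can support different areas of endemism.
* **Scheme robustness** (`compare_schemes()`): the full pipeline per scheme on
  one shared grid, with pairwise Pearson correlation of the consensus
  surfaces. The sampled mode of `map_correlation()` reproduces the coarse-cell
  protocol used for cross-method comparison (2° cells, 10 random points per
  cell, per-cell means correlated); cellwise mode is the deterministic
  default. Note the correlation depends on the evaluation window: computed
  over a mostly-empty far field it will differ from the same comparison over
  the occupied study window, so `compare_schemes()` accepts an explicit grid.
* **Grid matrix export** (`build_grid_matrix()`): the binary species × cell
  incidence matrix that grid-based methods start from, writable as CSV and as
  a TNT-style block (cells as terminals, species as characters, optional
  all-absent hypothetical root) for external parsimony analysis. This is
  comparison plumbing only; no parsimony or optimality search is implemented.

## The synthetic landscape generator

Real occurrence databases at this scale are dominated by rarity: in the
motivating use case roughly 40% of species are known from a single record and
another 45% from 2–15 records. `landscape_spec()` / `generate_dataset()`
emulate exactly that profile — the record-count bins default to 40/45/10/3/2%
for 1, 2–15, 16–60, 61–100 and >100 records — over a 20° × 20° continental
window holding K = 5 planted endemic centers of 30 species each plus 15
widespread species. Endemic records scatter about their center as a truncated
Gaussian (σ = radius/2, hard cut at the radius, 25 km by default). The 25 km
default is deliberate: a record-to-centroid distance can never exceed twice
the scatter radius, so every planted species is guaranteed to fall in the
[0, 50] km class and the planted ground truth maps one-to-one onto the
smallest-scale category, which is what makes exact recovery testable. Centers
are auto-placed at least 8 scatter radii apart (200 km = 4 × the 50 km class
radius).

The generator emulates the *statistical* structure of a real database, not its
spatial biology: records are isotropic about their center, sampling effort is
spatially uniform, there is no georeferencing error, no road-and-museum
collection bias, no environmental gradient, and no correlation between range
size and record count beyond the planted classes. Passing the recovery tests
therefore shows the machinery is correct — planted overlap structure is found
where it was planted, and nowhere else — not that any particular empirical
dataset will yield clean areas; on real data the diagnostics above are the
guard rails.

## Problem sizes and test design

The test suite and the acceptance script run entirely on synthetic data at
desk scale: grids up to roughly 250 × 250 cells at 0.1–0.25°, landscapes of
150–165 species and ~1,500–2,500 records, 20 generator seeds for the recovery
experiment, 100 rarefaction randomizations, and 30–100 random configurations
for the brute-force kernel cross-check. These sizes were chosen so the full
pipeline exercises every code path in seconds per run while keeping
Monte-Carlo error well inside the asserted margins; all of them scale up
linearly in cells × species for production use.

## Known limitations

* The circular area of influence misrepresents strongly elongated or disjoint
  ranges (screen first; split disjoint species; clip outputs to habitat where
  that is defensible). Perfectly congruent elongated ranges would be found but
  drawn as a circle.
* The arithmetic-mean centroid is not meaningful across the antimeridian;
  the package warns and leaves unwrapping to the user (the intended domain is
  continental).
* Min–max standardization ties each category's scale to its own extremes;
  with very few species in a category the standardized surface can be noisy,
  which is visible in the per-category rasters that `build_all_surfaces()`
  retains.
* Delimited areas are raster components: sub-cell precision of their
  boundaries is limited by the display grid, and areas smaller than one cell
  carry no contour ring (they are still reported, with a degenerate polygon
  in the GeoJSON writer).
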