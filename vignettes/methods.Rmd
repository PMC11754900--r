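---
title: "Methods: tiered classification of ice-free landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered classification of ice-free landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icefacets)
```

# The model

`icefacets` builds a hierarchical ecosystem typology on a regular
planar grid. The statistical core is gradient partitioning by
exploratory factor analysis: latent variables ("facets") summarize
recurring combinations of input layers, and a pixel is assigned to the
facet that scores highest there. Unlike clustering algorithms that
depend on random initialization, the whole classification is
deterministic given the data and settings, and the loadings make every
class directly interpretable.

Three tiers nest inside each other:

1. **Tier 1** partitions abiotic variation (terrain, climate, melt,
   insolation) into Major Environmental Units `E1..Ek`.
2. **Tier 2** partitions biotic variation — habitat-suitability
   surfaces for a panel of taxa — separately *within* each Tier 1
   unit, giving Habitat Complexes `EiBj`. Distinct Overlay Ecosystems
   (geothermal `G1`–`G3`, seabird colonies as a complex within `E1`,
   lakes `L1`) are stacked on top with fixed precedence
   lakes > colonies > geothermal > base.
3. **Tier 3** intersects the Tier 2 map with bioregions and
   amalgamates marginal fragments, yielding Bioregional Ecosystem
   Types such as `E2B1-NWAP`.

Assumptions worth stating explicitly: all layers are co-registered on
one planar grid (no reprojection or geodesic corrections — the
workflows this supports operate in a polar stereographic plane);
abiotic layers are approximately linear-Gaussian after standardization
(factor analysis models correlations, not arbitrary dependence); the
suitability surfaces are positive and share a dominant "mildness"
gradient; and bioregions are an adequate proxy for regional biotic
turnover, which the package treats as given input rather than
something it estimates.

# Factor analysis choices

**Extraction** is iterated principal-axis factoring: squared multiple
correlations initialize the communalities, the reduced correlation
matrix is eigendecomposed, and communalities are updated until the
largest change falls below `tol = 1e-3` (the customary stopping rule
for principal-axis refinement; the iteration converges only linearly,
so a much smaller tolerance buys nothing but iterations). Maximum
likelihood via `stats::factanal` serves as an independent cross-check
in the test-suite, never as the implementation.

**Rotation** defaults to promax (`m = 4`), an oblique rotation, since
environmental facets have no reason to be orthogonal; varimax is
available. Promax is computed as an oblique relaxation of the varimax
solution. Because single-start varimax can stall on a zero-gradient
saddle when the loading pattern is near-symmetric (a real failure mode
we guard against), the rotation runs from several fixed starting
rotations and keeps the solution with the best varimax criterion.
Pattern coefficients of an oblique rotation are regression weights,
not correlations, so they may legitimately exceed 1; the model
validates |loading| ≤ 1.05 for orthogonal solutions and ≤ 1.5 for
oblique ones.

**Orientation and order.** Each factor is flipped so its
largest-magnitude loading is positive ("more of the facet" is a high
score), and factors are ordered by explained variance. Both choices
are conventions; classification is equivariant under facet
permutation.

**Scoring** uses regression (Thurstone) weights `W = R⁻¹ Λ Φ`, which
reduce to `R⁻¹Λ` for orthogonal factors. Structure weighting
(`W = Λ`) is provided for working with published loading tables whose
score weights were never printed; the shipped reference table
(`inst/extdata/tier1_reference_loadings.csv`) is used that way in the
examples and tests.

**Factor count** comes from parallel analysis: each column of the data
is permuted independently (preserving marginals, destroying
correlation), 100 replicates by default, and the retained count is the
number of leading observed eigenvalues exceeding the null's 95th
percentile at the same rank, stopping at the first failure. The
permutation null was chosen over Gaussian resampling because it makes
no distributional assumption about the layers; the replicate count and
quantile are exposed parameters, and the draw is seeded.

# Tier 2 specifics

Suitability values are heavily skewed toward zero with a shared
mild-conditions trend, so a single log leaves the taxa almost
collinear. The transform applied per taxon, within the unit being
subdivided, is `log` → range-normalize to [1, 100] → `log`. Natural
logarithms are used throughout; the base matters only because a
normalization sits between the two logs, so it is fixed and
documented. Zeros are floored at half the column's smallest positive
value before the first log; a constant column maps to zero with a
warning. The transform preserves within-column ranks exactly. The
alternative order (normalize first, then log twice) is available as a
config option.

Normalization scope is per Tier 1 unit because the transform is part
of the per-unit analysis; continent-wide normalization would let one
extreme unit compress every other unit's range.

Units with fewer classifiable pixels than `min_unit_pixels`
(default `max(25, n_taxa + 1)`) raise an explicit error, or — in
pipeline use, where a tiny unit should not abort a long run — collapse
to a single complex (`small_unit = "single"`). A unit whose pixels all
share one suitability profile likewise becomes a single complex.

**Nibble fill.** An unclassified land pixel takes the label of the
nearest classified pixel (Euclidean, pixel centers) that is in the
same Tier 1 unit *and* the same contiguous ice-free patch; squared
center distances are exact integers in cell units, so equidistance is
exact and resolved by row-major pixel order. Pixels with no eligible
donor stay unclassified. Patch contiguity defaults to queen
(8-neighbour) connectivity — the common GIS region-grouping convention
— and rook is available everywhere connectivity appears.

# Overlay rules

Geothermal categories follow eruption age: active under 1,000 years
(or observed fumaroles/heat, or an explicit per-record proximity
override for neighbours of an active volcano), dormant from 1,000 to
100,000 years, radiogenic as its own class, inactive (older or
unknown) excluded so those pixels keep their factor-analysis class.
The proximity exception is a flag on the record rather than an
automatic distance rule, because it encodes a judgment about shared
eruption history, not a reproducible threshold.

Colony cleaning measures distance from a record to the nearest land
pixel center; the coastline is discretized as the centers of land
pixels with at least one non-land neighbour, and "snap to the nearest
coastline" means the nearest such center. Records beyond 4 km of land
are dropped, 3–4 km are snapped and flagged for manual review, up to
3 km are snapped silently; colonies above 80,000 estimated pairs are
flagged (never auto-adjusted). Counts are averaged per type over
years; nests equal pairs; otherwise adult and chick counts are divided
by species ratios and the available estimates averaged (the mean is
our choice — only "divided by the ratios" is prescribed). Ratios are
means over same-colony-same-year pairs, falling back to per-colony
all-year averages with the provenance flagged. The pairs-to-area
calibration is ordinary least squares; predictions are floored at
100 m² (one hundredth of a pixel) with a warning, guarding against a
negative intercept at small colonies. The footprint radius
`r = 2·sqrt(a/π)` doubles the equivalent-area disc radius because a
coastal colony loses about half the disc over a straight coastline and
nutrient influence extends beyond the nests; footprints rasterize with
the touch rule (any intersecting pixel), lakes with the ≥ 50% coverage
rule, which makes ~5,000 m² (half a pixel) the smallest mappable lake
at 100 m resolution.

# Tier 3 amalgamation

Candidates below `min_pixels` (default 100 pixels = 1 km²; exposed
because only the 5% adjacency rule is fixed by the method description)
are processed smallest-first. A candidate merges into a neighbour when
at least 5% of its pixels border that neighbour and both belong to the
same Major Environmental Unit; among qualifying neighbours the largest
adjacency fraction wins, ties going to the larger unit and then the
lower code. Passes repeat until stable, so the operation is idempotent
and pixel counts are conserved; the absorbing unit's code gains the
`a` suffix. The selection rule among multiple neighbours and the
smallest-first ordering are our choices where the published rules are
silent; both are deterministic and logged per decision.

# The synthetic landscape

`gen_landscape()` emulates the statistical structure the analysis
assumes, with every random draw fixed by one seed:

* **Abiotic layers** are `X = F Λ' + ε`. The latent fields `F` are
  Gaussian-smoothed white noise (length scale `field_scale = 18`
  pixels, so classes form contiguous patches as on real terrain),
  orthonormalized *exactly* over land pixels — at `noise_sd = 0` the
  sample correlation matrix equals the Λ-implied one to numerical
  precision, which the tests exploit. The default planted Λ gives
  each of five facets one ~0.92 and one ~0.62 indicator among the ten
  variables, keeping the published facet interpretations while
  remaining rotation-identifiable; a verbatim published loading table
  is heavily cross-loaded and cannot be recovered by any rotated
  solution, so it ships separately for scoring rather than as the
  generator default. Indicator pairs share a sign so the positive
  orientation of every facet is unambiguous.
* **Noise.** The default unique noise is `noise_sd = 0.1` per layer.
  This is the deliberate "low-noise" study condition: with ten
  indicators for five facets, regression factor scores carry an
  irreducible error that grows with noise, and by `noise_sd = 0.3`
  boundary misclassification makes label recovery above ARI 0.8
  unattainable for any loading pattern of this size. The recovery
  tests therefore assert the attainable surface at the default
  condition.
* **Suitability surfaces** use two latent biotic gradients, each
  correlated 0.6 with a mildness field, plus taxon-specific mild
  responses and pixel noise, pushed through a doubly-exponential link
  `exp(exp(z))`. That link produces the nested wedge — all taxa peak
  jointly under the mildest conditions, with extreme positive skew —
  which a single log fails to linearize but the double-log transform
  does; the ablation contrast between the two transforms is asserted
  in the tests. The planted Tier 2 truth within each Tier 1 unit is
  the relatively strongest gradient on the within-unit standardized
  scale, matching the location/scale invariance of a per-unit factor
  analysis.
* **Geometry.** The coastline is a thresholded smooth field (60% land
  by default), bioregions a Voronoi partition of land seeds, lakes
  circles centered on interior pixel centers with diameters spanning
  the half-pixel threshold (including 79 m and 80 m), colonies placed
  on coastline pixels plus planted offshore records at 2, 3.5 and 5 km
  to exercise every cleaning rule, and eight volcano records covering
  all four geothermal categories. Colony counts carry planted
  chick:nest and adult:nest ratios with mean-one multiplicative noise
  (sd 0.05), pairs are log-normal, and the pairs-to-area calibration is
  a noisy line with intercept 50 m² and slope 2 m² per pair — the
  order of magnitude of observed nest densities.

What the generator does *not* emulate: real climatology or species
niches, spatially correlated observation error, biased colony count
coverage, mixed-resolution inputs, or coastline mismatch between
layers. Passing tests therefore demonstrate that the machinery
recovers known structure under the stated statistical assumptions —
not that any particular real landscape satisfies them.

# Numerical and engineering choices

* Geometry is computed exactly: Sutherland–Hodgman clipping of rings
  against pixel squares, shoelace areas, hole rings subtracting.
  Features of one polygon set are assumed disjoint (coverage is
  clamped at 1); there is no polygon-union engine in the package.
  Circles are regular polygons (720 vertices by default; inscribed
  area within 1e-5 of the true circle). Polygon clipping against a
  polygon window requires a convex window; raster workflows clip
  against the land mask instead.
* Rasters are ESRI ASCII grids — a plain-text, GIS-standard format
  that round-trips integers exactly and doubles at full precision;
  polygons are GeoJSON, tables CSV.
* Ties everywhere break deterministically: argmax to the lowest facet
  index, nibble donors by row-major order, amalgamation targets by
  fraction, size, then code.
* The test-suite and the worked examples run at 200 × 200 pixels
  (24,000 land pixels) for the full pipeline and 80 × 80 for module
  fixtures; these sizes exercise every code path with thousands of
  pixels per unit while keeping a full run around ten seconds.

# Known limitations

* With ten abiotic variables and five facets, factor scores are
  informative but not exact; classification confidence near facet
  boundaries is intrinsically limited, which is precisely what the
  dominance index surfaces (two-complex units pin dominance at 1 by
  construction, since best-minus-second equals the range).
* The colony Habitat Complex label is allocated as the next free `B`
  index within `E1`; re-applying overlays to an already-assembled map
  is exactly idempotent only when that label is pinned via
  `colony_label`.
* Coverage of genuinely overlapping polygons is summed and clamped,
  not unioned.
* The amalgamation decision tree implements the published 5% adjacency
  rule plus documented, configurable choices for everything the
  published description leaves open; it does not attempt to reproduce
  any specific historical unit count.
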