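---
title: "Delineating management zones by clustering and smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating management zones by clustering and smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspzone)
```

## The problem

Variable-rate application of fertilizer, manure, seed or water needs the
field divided into a few contiguous *management zones* (MZs), each
homogeneous enough that a single input rate is appropriate. The raw
evidence is high-density proximal sensing — an online vis-NIR soil scanner
pulled along parallel transects roughly 12 m apart, logging soil fertility
attributes (MC, OC, Ca, CEC, K, Mg, Na, P, pH) every second (~0.8 m
along-line at 3 km/h) — optionally joined by satellite NDVI and combine
yield maps. Two features of these data drive every design choice in this
package:

* **Anisotropic sampling.** Sub-meter resolution along the line, 12 m
  between lines. Clustering raw points overweights the along-line
  direction, so attributes are first interpolated onto a common 5 × 5 m
  grid by ordinary kriging, which encodes the spatial correlation once.
* **Incommensurate units.** Ca lives in the thousands of mg/kg, pH around
  6–7. Any Euclidean-distance method applied to raw values clusters on Ca
  alone; range normalization puts each attribute (and, when used, the
  coordinates) on \[0, 1\].

## Pipeline

The recommended recipe, in order: (0) ordinary kriging of point samples to
the common grid (skipped for pre-gridded input); (1) range normalization;
(2) feature selection by Pearson cross-correlation; (3) clustering — k-means
by default; (4) island smoothing. `run_casp()` executes exactly this and
logs every default in force.

### Kriging (step 0)

The semivariogram is estimated by the method-of-moments
$\gamma(h_b) = \frac{1}{2N_b}\sum_{(i,j)\in b}(z_i - z_j)^2$ and fitted by
pair-count-weighted least squares; the default family is spherical, the
most common convention in this literature (the source work names only
"ordinary kriging", so family, lag count and neighborhood size are this
package's choices and are not claimed to replicate any particular field
product). Predictions solve the ordinary-kriging system over the 32
nearest samples with the unbiasedness constraint $\sum w_i = 1$ via a
Lagrange multiplier; duplicate coordinates are averaged first because they
make the system singular. The field mask keeps cells within `mask_radius`
(default 24 m = twice the line spacing) of a sample, bounding
extrapolation between transects. With a zero nugget the predictor
interpolates exactly; a constant field is reproduced everywhere — both are
enforced by tests.

### Normalization and feature selection (steps 1–2)

Normalization is $(v - \min)/(\max - \min)$ per column; a constant column
maps to zeros with a warning instead of erroring, so a degenerate
synthetic layer cannot kill the pipeline (Pearson correlation on such a
column *does* error, because r is undefined there). Selection is greedy in
a user-supplied priority order (CEC first by default, reflecting its
weight in soil-fertility interpretation): an attribute is kept iff its
|r| with every already-kept attribute is at or below the threshold
(default 0.7). Screening uses the absolute value — a strong negative
correlation is exactly as redundant as a positive one. On d ≤ 6 this
greedy rule provably equals the priority-lexicographic optimum, and the
test suite checks it against exhaustive subset search.

### Clustering (step 3)

All five algorithms are implemented in the package, deterministically:
ties between equidistant centroids or modes always resolve to the lowest
index, DBSCAN visits rows in order, and every stochastic step is driven by
the configured seed.

* **k-means** (default): Lloyd iterations, initial centroids drawn as k
  distinct data points, 10 restarts by default (40 in the optimality
  tests), empty clusters re-seeded at the point farthest from its
  centroid. The within-cluster SSE trace is non-increasing by
  construction and asserted per iteration.
* **Fuzzy C-means**: membership update
  $u_{ij} = 1/\sum_l (d_{ij}/d_{il})^{2/(m-1)}$, fuzziness m = 2 (the
  usual choice); a point coinciding with a centroid takes membership 1
  there. As m → 1 the hard labels collapse to k-means, which the tests
  exploit as an oracle.
* **Mean shift**: Gaussian kernel by default; bandwidth from the mean
  distance to the ⌈qn⌉-th nearest neighbor at q = 0.3 (on normalized
  nine-attribute field data this lands near 0.41, the value the source
  work reports from the same convention). Modes within h/2 merge in seed
  order.
* **Hierarchical**: agglomerative with single linkage by default — the
  literal "merge the smallest distance" rule — with complete/average/ward
  available because the source work does not state the linkage it ran.
  Single linkage is cross-checked against a minimum-spanning-tree oracle.
* **DBSCAN**: the neighbor count *includes the point itself* (mp = 3
  means "≥ 3 points in the ε-ball counting self") — stated explicitly
  because implementations differ. Unreachable low-density points get
  label −1 and are excluded from every validity metric. For gridded
  input the default ε is the grid cell size, the mean spatial scanning
  resolution of a raster.

Scenario names follow the `<algorithm>-<tokens>` grammar (`wn`/`nn`
normalization, `wc`/`nc` coordinates, `dec` feature decrease); the full
evaluation grid is 21 scenarios, with the un-normalized variant defined
only for k-means. Coordinates are *excluded* by default: kriging already
encoded the spatial correlation, and including x/y would count it twice.

### Validity metrics

DBI uses the standard reading $\frac{1}{k}\sum_i \max_{j \ne i}
(s_i + s_j)/d_{ij}$ (the j ≠ i qualifier is implicit in the source's
formula). Silhouette assigns 0 to members of singleton clusters, where
a(i) is undefined. Both are undefined below two effective clusters and
are reported as `n.v.` (NA) rather than raised as errors, because a
density method legitimately returning one cluster is a *result*. VRI is
$(1 - \sum_i A_i v_{C_i\theta}/v_\theta) \times 100\%$ with area-weighted
**population** (1/N) variances — the source of the index is ambiguous on
this point; population variance was chosen and is used consistently, and
at a single cluster it gives exactly 0. VRI is always computed on the raw
attribute rasters, never on normalized features; the pipeline enforces
this by type at the stage boundary.

### Smoothing (step 4)

Clustering output contains *islands*: fragments of one zone inside
another, smaller than any variable-rate actuator can respond to. Per
pass, for each label in ascending order, the island detector runs DBSCAN
on that cluster's cell-center coordinates with ε = cell_size·√2 + 1e−6
and mp = 3, which makes components exactly the 8-connected regions of the
grid (the equivalence is exploited by a flood-fill test oracle).
DBSCAN-outlier cells join the cluster of their nearest non-outlier cell;
components smaller than `island_size` are relabeled to the plurality
label of the outside neighbors of their edge cells, counted with
multiplicity so longer shared borders weigh more. Ties go to the lowest
label. Because relabeling can expose new sub-threshold fragments, passes
repeat to a fixed point (cap `max_passes`); the printed algorithm is
single-pass, and the iteration is this package's addition, logged per
pass in the audit trail. `island_size_from_area()` converts a machinery
active-control-unit area into the cell threshold.

## The synthetic world

No field data ship with the package, so `simulate_field()` provides the
test bed: contiguous zones from seeded Voronoi cells (or bands),
per-attribute surfaces = zone means + a stationary Gaussian random field
(circulant embedding, exponential covariance, 40 m practical range) +
white nugget noise, and transect sampling at 12 m × 0.83 m emulating the
scanner. Defaults are fixed once: nine soil attributes at realistic
scales; the base-cation group (Ca, CEC, Na, pH) shares a zone-mean
ordering and latent fields so its members correlate above 0.7 — giving
feature selection real work — while the remaining attributes follow
distinct zone-mean orderings (tuned for four zones) with a larger
within-zone share, keeping their correlations moderate.

What a green test does establish: the algorithms solve their optimization
problems (checked against enumeration, graph, MST and brute-force
oracles), the metrics match hand calculations, smoothing certifies its
postcondition, and the full pipeline recovers well-separated planted
zones (ARI ≥ 0.9). What it does not: that the defaults reproduce any real
field's zone map — the source work's per-field tables were computed on
proprietary data, and its own authors note the exact settings (linkage,
restarts, variogram families) are unreported. The simulator also omits
real-data features: no attribute non-stationarity or trends, no
measurement drift along transects, no anisotropic covariance, no missing
swaths.

## Numerical choices and degenerate inputs

* Variogram fitting: bounded multi-start quasi-Newton WLS, weights = pair
  counts; range bounded by twice the maximum lag; a pure-nugget start is
  always included so flat semivariograms fit cleanly.
* Kriging: if the neighborhood system is singular after de-duplication, a
  tiny ridge is added before failing outright.
* FCM stops on max membership change < tol (1e−6); k-means on unchanged
  assignments; mean shift on max displacement < 1e−4·h.
* Constant columns: normalized to zeros (warn); correlation errors;
  zero-variance attributes are skipped by VRI (warn).
* All label ties, everywhere, resolve to the lowest label; this plus
  row-order visiting makes every algorithm reproducible bit-for-bit from
  config + seed.

## Limitations

Scenario evaluation is heuristic — DBI/Silhouette/VRI score compactness
and variance reduction, not agronomic value; the recommended
`kmeans-nc-dec` default follows the stability argument, not a universal
optimum. Hierarchical clustering is O(n²) in memory and is intended for
desk-scale grids (≤ ~10⁴ cells). No CRS handling: all coordinates must
already be projected meters. Polygonization and prescription-file export
are out of scope.
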