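---
title: "Unsupervised particle shape metrology from electron micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised particle shape metrology from electron micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoshapes)
```

## The problem

Transmission electron microscopy (TEM) resolves individual nanoparticles
well enough to measure their projected size and shape, but a statistically
representative characterization needs hundreds of particles per condition,
and manual outlining does not scale. `nanoshapes` automates the chain from
a calibrated 2-D micrograph to a per-shape-class summary table:

1. **Segmentation** — dynamic (locally adaptive) thresholding separates
   particles from an inhomogeneous background.
2. **Contour extraction** — 8-connected components of the binary mask are
   traced into closed outer contours (Moore neighbour tracing); a Canny
   edge detector is available as an independent edge map and cross-check.
3. **Aggregate rejection** — contours whose solidity (area over
   convex-hull area) falls below a cutoff are discarded as overlapping
   aggregates, as are contours truncated by the image frame.
4. **Shape parameterization** — each kept region is described by the seven
   Hu moment invariants plus the metrology quantities: equivalent-circle
   diameter, moment-ellipse aspect ratio, eccentricity.
5. **Classification** — average-linkage hierarchical clustering over the
   prepared Hu features; the number of shape classes is chosen
   automatically from the common local extrema of three internal cluster
   validity indexes (Silhouette, Davies–Bouldin, Calinski–Harabasz).
6. **Reporting** — per-class counts, fractions, and mean ± sd of size,
   aspect ratio and eccentricity, plus histograms and overlay images.

Because suitable public micrographs with per-particle ground truth do not
exist, the package includes a synthetic micrograph generator
(`render_scene()`) that produces calibrated images *and* a per-pixel truth
raster, so every stage is testable quantitatively.

## Segmentation model

A global intensity threshold fails whenever the background varies across
the field of view (support-film thickness, uneven illumination): any
single threshold either swallows particles in the dark region or spills
background in the bright one. Dynamic thresholding compares each pixel
against a *local* background statistic computed over a sliding window,
minus an offset:

* `window_px` — window side. Default: about 4× the expected particle
  diameter (auto-estimated by `auto_threshold_config()` from a coarse
  first pass). A window much larger than one particle ensures the local
  statistic reflects background, not particle interior; much smaller and
  particle interiors are hollowed out.
* `offset_c` — subtracted from the local statistic. Default: 2× the
  robust noise estimate (1.4826 × MAD of the high-pass residual), i.e.
  a pixel must be darker than its local background by twice the noise
  level to count as foreground. This ties the threshold to measured image
  quality rather than to an absolute intensity.
* Local statistic: Gaussian-weighted mean (default) or box mean; border
  pixels use edge replication, avoiding spurious frame-dark artifacts.
* Cleanup: morphological opening (disc radius 1 px), hole filling, and
  removal of components below `min_area_px` (default 20 px). Cleanup is
  idempotent and entirely config-exposed.

## Convexity filtering

Isolated nanoparticles of the kinds targeted here project to convex
shapes; touching or overlapping particles produce a merged silhouette
with a concave waist. Solidity — region area divided by convex-hull
area — is rotation- and scale-free, so a single cutoff separates the
two. The default cutoff is 0.96, set by measured margins: isolated
particles segmented from synthetic scenes score ≥ 0.98, while fused
near-round pairs overlapping by 20–50% of a radius score 0.88–0.95
(counter-intuitively, the *deeper* the overlap the shallower the
concave waist, so deep-overlap pairs are the hardest case and bound the
cutoff from below). The
hull area is computed as the lattice-point count of the hull polygon
(Pick's theorem), which is commensurate with pixel-count areas: a
digitally convex region scores exactly 1, and rasterization cannot push
solidity above 1 + 1e-3. Border-touching contours are rejected
unconditionally because their shapes are truncated by the field of view;
this is required for unbiased shape statistics even though it slightly
reduces counts.

The filter deliberately does **not** split aggregates (no watershed or
morphological surgery): rejecting them keeps the shape statistics clean
while retaining enough isolated particles for significance. The
consequence, inherited by design, is that genuinely concave particle
shapes cannot be distinguished from aggregates.

## Shape features

Central normalized image moments `eta_pq` are computed over the filled
region (far less rasterization-sensitive than boundary-line moments), and
combined into the seven Hu invariants `phi_1..phi_7`, which are invariant
to translation, scale and rotation. Reported metrology:

* equivalent diameter `2*sqrt(area/pi) * nm_per_px` — the diameter of the
  circle of equal projected area;
* aspect ratio `sqrt(lambda1/lambda2)` and eccentricity
  `sqrt(1 - lambda2/lambda1)` from the eigenvalues of the second-moment
  matrix; the two satisfy `ecc^2 = 1 - 1/AR^2` exactly.

### Preparing Hu features for clustering

This is the one place where the obvious choices fail, and the package's
default departs from both naive options deliberately. The raw invariants
span many orders of magnitude (`phi_1 ~ 0.16`, `phi_5 ~ 1e-16`), so raw
Euclidean distances are dominated by `phi_1`/`phi_2` alone; worse, for
near-symmetric shape populations the within-class spread of `phi_2` is
comparable to between-class gaps, and single extreme particles hijack the
top of the average-linkage dendrogram. The standard signed-log transform
`h_i = -sign(phi_i) log10|phi_i|` fixes the dynamic range but creates the
opposite pathology: invariants that vanish in the continuum for symmetric
shapes (e.g. `phi_3..phi_7` of regular polygons and rods) have raster
values that are pure discretization noise, and the log maps that noise
onto large, sign-flipping coordinates that dominate every distance.
Measured end-to-end on synthetic two-family scenes, both naive options
select the wrong number of clusters and score 26–55% label agreement.

`feature_matrix()` therefore prepares the default feature as signed-log
Hu with three steps, all config-exposed:

1. **Noise-floor masking** (`mask_floor = 1e-5`, `mask_prob = 0.9`): a
   dimension whose `|phi_i|` stays below the floor for ≥ 90% of particles
   is dropped for the whole dataset — it carries no shape information at
   the available resolution. The floor sits two to three decades above
   the raster noise of third-order invariants for ~30 px particles and
   two decades below genuine third-order signal (e.g. triangles'
   `phi_3 ~ 1e-3`).
2. **Clamping**: in kept dimensions, `|phi|` is clamped from below at the
   floor before the log, so sub-noise values map to one bounded point
   instead of a heavy tail of pseudo-precise logs.
3. **Standardization**: each kept dimension is z-scored so no single
   invariant dominates the metric.

With this preparation the synthetic analogue of a mixed
hexagon/rod sample (75 + 81 particles) is recovered as exactly two
classes with ≥ 98% best-permutation agreement on 10/10 generator seeds,
where the naive features fail. Raw (`feature = "hu"`) and unmasked
variants remain available for comparison.

## Clustering and choosing k

Average linkage (UPGMA) is built from scratch with Lance–Williams
updates; ties are broken lexicographically by smallest member index, so
results are deterministic across platforms. The implementation is tested
for exact equality against a naive O(n³) re-agglomeration oracle and
against `stats::hclust(method = "average")` heights.

For each cut `k = 2..k_max` (default `k_max = 10`; all realistic particle
populations here have k ≤ 5) three internal validity indexes are
evaluated in feature space: Silhouette and Calinski–Harabasz (maximize)
and Davies–Bouldin (minimize). The chosen k is the smallest common local
extremum of all three; endpoints of the k range count as extrema when
they beat their single neighbour. When the three indexes share no
extremum the package falls back to the smallest k shared by two of them
(`majority`), then to the global Silhouette maximum
(`silhouette_fallback`); the rule actually used is recorded in the
`cvi_profile`, so a fallback is always visible in the output.

## The synthetic generator

`render_scene()` emulates the three imaging situations the pipeline is
designed around, via `scene_preset()`:

* `"dispersed_polygons_rods"` — 1024² px at 1 nm/px, bright-field
  polarity, 156 particles: regular hexagons (33.6 ± 2.0 nm, aspect ratio
  1 by symmetry) and rods (38.1 ± 1.7 nm, AR 1.37 ± 0.08) in a 75:81
  mix, over a 30% linear background gradient with noise σ = 5% of the
  particle contrast. This reproduces the regime where global thresholding
  provably loses particles and dynamic thresholding recovers all of them.
* `"dense_round"` — 1200² px at 0.3 nm/px, 125 particles from five
  well-separated shape families (triangles, squares, rods of AR 1.4,
  2.0, 2.8; all ~11.8 nm), low contrast (30 over background 150),
  testing multi-class recovery.
* `"dark_field_cubes"` — 1024² px at 0.25 nm/px, bright particles on a
  dark radial-gradient background, 110 cubes (10.4 ± 1.1 nm, AR
  1.06 ± 0.04) with 20% of particles placed as overlapping aggregate
  pairs (center separation short of touching by 20–50% of the smaller
  radius), exercising polarity handling and convexity filtering.

Shapes are calibrated exactly: each generated polygon is rescaled along
its principal axes so its continuum moment aspect ratio equals the
requested value, then isotropically so its equivalent diameter matches.
Rasterization uses 4×4 subpixel coverage sampling (anti-aliasing),
mimicking finite edge sharpness; Gaussian noise is added on top. A single
integer seed drives every stochastic draw, and rendering is bit-identical
for a fixed seed.

What the generator does *not* emulate: physical image formation
(defocus/contrast transfer, multislice scattering), structured background
texture such as amorphous carbon, chains of three or more aggregated
particles, and concave particle shapes. Passing the synthetic tests
therefore demonstrates the pipeline's geometric and statistical
correctness, not robustness to every experimental artifact; on real
micrographs the segmentation parameters (`window_px`, `offset_c`,
`min_area_px`) remain the user's responsibility, with
`auto_threshold_config()` as a starting point.

## Numerical choices and degenerate inputs

* Moments use 0-based pixel-centre coordinates; areas are pixel counts.
* `hu_invariants()` reports `h_i = 0` when `|phi_i| < 1e-30` (exact-zero
  convention); the clustering clamp above is separate and dataset-level.
* 1-px-wide regions have a vanishing minor eigenvalue; they are flagged
  `degenerate` and excluded from clustering rather than given infinite
  aspect ratios.
* Clustering requires at least `k_max + 1` particles; Davies–Bouldin
  raises an error on coincident centroids, Calinski–Harabasz returns
  `Inf` on zero within-cluster scatter; `select_k()` treats those values
  as worst-case and continues.
* 8-connectivity for foreground components, 4-connectivity for
  background (hole filling), the standard pairing that avoids
  topological paradoxes.
* Problem sizes in tests and in the acceptance script (hundreds of
  particles at ~1 Mpx) were chosen to mirror realistic per-image particle
  counts while keeping a full run in tens of seconds on one CPU.

## Known limitations

* Concave isolated particles are rejected as pseudo-aggregates (inherent
  to convexity filtering).
* Aggregates are rejected, not split; heavily aggregated samples lose
  statistics accordingly.
* Overlapping pairs of *faceted* particles (e.g. cubes) with
  near-aligned faces can form a nearly convex union that no convexity
  statistic detects; the ≥ 95% aggregate-rejection guarantee holds for
  near-round particles, and faceted samples should expect a small
  fraction of undetected two-particle unions.
* Hu invariants describe 2-D projections only; no 3-D shape inference.
* At low magnification (few pixels per particle), higher-order invariants
  are below the raster noise floor and the classifier effectively sees
  only elongation and roundness; genuinely subtle shape differences need
  more pixels per particle.
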