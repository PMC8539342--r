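# nanoshapes

Statistically representative size and shape metrology of nanoparticles
from transmission electron micrographs, for microscopists and materials
chemists who need per-shape-class statistics over hundreds of particles
without manual outlining.

Given a calibrated 2-D grayscale micrograph (bright-field TEM with dark
particles, or ADF-STEM with bright particles), the pipeline:

1. separates particles from an inhomogeneous background by **dynamic
   (locally adaptive) thresholding** — each pixel is compared against a
   local background statistic `B_w(x)` over a window `w`, minus an offset
   `c` tied to the measured noise: foreground where `I(x) < B_w(x) - c`
   (sign flipped for dark-field);
2. traces each 8-connected component into a closed **particle contour**
   (Moore boundary following; a from-scratch Canny detector provides an
   independent edge map);
3. rejects aggregates and border-truncated particles by **convexity
   filtering**: solidity = area / convex-hull area; overlapping convex
   particles form concave unions with solidity below the cutoff;
4. parameterizes each kept particle by the seven **Hu moment
   invariants** φ₁..φ₇ (translation-, scale- and rotation-invariant
   functions of the normalized central moments η_pq) plus the metrology
   quantities: equivalent diameter `2·√(area/π)·nm_per_px`, moment-ellipse
   aspect ratio `√(λ₁/λ₂)` and eccentricity `√(1 − λ₂/λ₁)`;
5. classifies shapes by **average-linkage hierarchical clustering**
   (UPGMA) of the prepared Hu features, choosing the number of classes k
   automatically as the smallest common local extremum of three internal
   cluster validity indexes — Silhouette and Calinski–Harabasz (maxima)
   and Davies–Bouldin (minimum) — with documented fallbacks;
6. reports per-class count, fraction, and mean ± sd of size, aspect
   ratio and eccentricity, plus histogram data and overlay images.

A synthetic micrograph generator with per-particle ground truth
(`render_scene()`, `scene_preset()`) makes every stage quantitatively
testable; see the vignette `vignettes/particle-shape-metrology.Rmd` for
the model details and design choices.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "nanoshapes", load_package = "installed")'
```

## Worked example

Render the built-in dispersed-scene preset — 156 well-dispersed particles,
a mixture of hexagonal platelets (33.6 ± 2.0 nm) and rods (38.1 ± 1.7 nm,
aspect ratio 1.37 ± 0.08), over a 30% illumination gradient — and run the
full pipeline:

```r
library(nanoshapes)

sc  <- render_scene(scene_preset("dispersed_polygons_rods", seed = 1))
res <- analyze_micrograph(sc$image)
res
#> <nanoshapes_result> 156 contours, 155 kept, 2 clusters (rule: common_extrema)
#>  cluster count     rate size_mean  size_sd aspect_ratio_mean aspect_ratio_sd
#>        0    80 0.516129  38.41961 1.743529          1.370695      0.07015408
#>        1    75 0.483871  34.24159 2.136434          1.010066      0.01576270
#>  eccentricity_mean eccentricity_sd
#>          0.6796787      0.04036362
#>          0.1285105      0.05194856
```

Cluster 0 (80 particles, 51.6%) is the rod class: mean diameter
38.4 nm, aspect ratio 1.37. Cluster 1 (75 particles, 48.4%) is the
polygon class: 34.2 nm, aspect ratio 1.01. Both match the planted
populations (one rod was dropped by the convexity filter at this seed
because its contour grazed another particle). Agreement with the
ground-truth labels is 99.4% under the best cluster-id permutation
(`label_agreement()`), and the CVI profile (`res$cvi`) records which
selection rule fired.

From the shell, the same pipeline is available as a thin CLI:

```sh
Rscript inst/scripts/nanoshapes simulate --preset dispersed_polygons_rods \
    --seed 1 --out-image scene.tif --out-truth truth.csv
Rscript inst/scripts/nanoshapes run --image scene.tif --nm-per-px 1 \
    --polarity dark_particles --out-dir results/
```

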