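---
title: "Epithelial sheet morphometry: models, scores, and group comparison"
author: "epimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epithelial sheet morphometry: models, scores, and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimorph)
```

## The problem

Healthy epithelial monolayers — the retinal pigment epithelium (RPE) is the
motivating example — are honeycomb-like: cells are near-hexagonal, uniform
in size, and each has about six neighbors. Degenerating or stressed
epithelia lose this order: cells enlarge, size spread grows, and outlines
drift away from the regular hexagon. `epimorph` quantifies this from
segmented flatmount images (integer label masks, one label per cell) and
tests group differences while respecting that cells are nested in images
which are nested in animals.

The package has three layers:

1. **tessellation i/o** — label images (TIFF/PNG) or GeoJSON polygon sets
   are converted to per-cell polygons with a neighbor graph, and cells on
   the image border or in annotated damaged regions are excluded;
2. **morphometrics** — per-cell descriptors including the 0–10
   polygonality and hexagonality regularity scores;
3. **group statistics** — mixed-model mean comparison, a robust
   residual-from-median variance comparison, Bonferroni–Dunn correction,
   Tukey pairwise contrasts and age trends.

A synthetic epithelial-sheet generator with exact vector ground truth
stands in for real flatmounts throughout validation.

## Per-cell shape metrics

For each cell with polygon outline we compute the area $A_{cell}$
(shoelace formula), the perimeter $P_{cell}$, the convex-hull area
$A_{hull}$ and perimeter $P_{hull}$, solidity $A_{cell}/A_{hull}$, the
maximum and minimum Feret (caliper) diameters from the hull (rotating
calipers), and the moment-ellipse descriptors: with central second area
moments the equivalent ellipse has semi-axes $a \ge b$, aspect ratio
$a/b$ and eccentricity $\sqrt{1-(b/a)^2}$. The neighbor count
$N_{neighbors}$ is the cell's degree in the adjacency graph.

### Regularity scores

The polygonality score compares a cell to the regular $N$-gon, where $N$
is its neighbor count. From the regular-polygon identity
$A = \tfrac{N}{4}s^2\cot(\pi/N)$, the regular $N$-gon of area $A_{cell}$
has perimeter $P_{ref} = N\sqrt{4A_{cell}/(N\cot(\pi/N))}$. The two
sub-ratios are

$$PSR = \frac{P_{cell}}{P_{hull}}\left[1-\left|1-\frac{P_{cell}}{P_{ref}}\right|\right],
\qquad
PAR = \frac{A_{cell}}{A_{hull}}\left[1-\left|1-\frac{4A_{cell}}{N\,(P_{cell}/N)^2\cot(\pi/N)}\right|\right],$$

and the score is $10\,(PSR+PAR)/2$. The hexagonality score is the same
construction with $N$ fixed at 6 — the honeycomb reference. A regular
$N$-gon with $N$ neighbors scores exactly 10; a square scores about 8.96
against the hexagon; scores fall as cells elongate or wrinkle.

```{r scores}
g <- basicGeometry(regularPolygon(6))
hexagonalityScore(g$perimeter, g$area, g$hull_perimeter, g$hull_area)$score

gs <- basicGeometry(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
hexagonalityScore(gs$perimeter, gs$area, gs$hull_perimeter, gs$hull_area)$score
```

Two numerical points deserve care:

* **No clamping by default.** Extremely elongated cells can drive a
  bracket negative, so scores below 0 are possible and are reported raw
  to preserve ordering; `clamp = TRUE` floors the sub-ratios at 0.
* **The sub-ratio bound.** On convex cells ($P_{cell}=P_{hull}$,
  $A_{cell}=A_{hull}$) each sub-ratio is $1-|1-x| \le 1$ and the score is
  at most 10 with equality only for the regular reference polygon. On
  strongly concave outlines the factor $P_{cell}/P_{hull}>1$ can push
  $PSR$ marginally above 1; epithelial cells are near-convex, so this is
  a corner case, but it is why the bound is asserted only for convex
  shapes in the test suite.

## From label image to polygons

Pixels are treated as half-open unit squares ($x$ = column, $y$ = row,
origin top-left), so the traced staircase polygon of a label has
shoelace area exactly equal to its pixel count times `pixelSize^2` — a
bookkeeping identity the tests enforce per label. Multi-fragment labels
abort the run (they signal segmentation failure rather than biology), as
do labels with holes.

The staircase perimeter of an oblique edge overestimates the true length
(up to the factor $|\cos\theta|+|\sin\theta|$, about +24% for a hexagon's
oblique edges), which depresses raster hexagonality scores relative to
vector truth. `extractCellPolygons(smooth = TRUE)` therefore offers
Douglas–Peucker simplification with a default tolerance of 1.5 px —
tolerances at or below 1 px cannot absorb the unit staircase steps of a
digital straight line — followed by rescaling the simplified ring about
its centroid to restore the exact pixel-count area, which is the
unbiased area estimate. Smoothing is off by default so that the default
pipeline remains the deterministic pixel-area convention; raster-vector
concordance checks switch it on. Within-study group comparisons are
unaffected by this choice because the staircase bias is common to all
groups.

### Neighbors

The source analyses do not pin down an operational adjacency rule, so
the package defines one: cells $a$ and $b$ are neighbors when at least
`minSharedPx` (default 3) pairs of pixels face each other across their
boundary, either directly 4-adjacent or separated by exactly one
background pixel. The one-pixel allowance matches the 1-px membrane
skeletons drawn by border-segmentation networks; the 3-pair threshold
discards corner-touch artifacts. Border and damaged cells are excluded
from metric reporting *after* the graph is built, so a retained cell's
neighbor count includes excluded neighbors — their geometry is
truncated, their adjacency is real.

## The synthetic generator

`generateSheet()` places seeds on a triangular lattice with spacing
matched to the target cell area, perturbs them with isotropic Gaussian
jitter of SD `jitterSigma` × spacing, optionally removes a
`dropoutFraction` of seeds (the Voronoi diagram remains space-filling,
so dropout creates enlarged cells), computes the Voronoi tessellation
clipped to the window, and applies `lloydIterations` steps of centroidal
relaxation. The unjittered lattice yields exact regular hexagons —
hexagonality 10 and six neighbors for every interior cell — so the
generator spans the full range from honeycomb to disorder with two
interpretable knobs. Clipping is exact (half-plane clipping with edge
provenance), which gives every cell its true neighbor list and exact
area/perimeter as ground truth.

Defaults emulate a murine RPE flatmount field: 350 × 350 µm windows,
250 µm² cells (~16 µm across), jitter 0.15 (mild wild-type
irregularity), rasters at 3 px/µm (~50 px per cell diameter). Rasters
label each pixel by its nearest seed (exact for Voronoi cells); a 1-px
membrane is carved by eroding the smaller-label side of each boundary,
and diagonal-only discretization tips at sharp corners are cleaned up by
a run-based connected-component pass so every label stays 4-connected.

`simulateCohort()` nests this generator in a genotype × age × mouse ×
image design. Effect multipliers act per genotype × age cell on target
area, jitter and dropout; a per-mouse lognormal factor (sdlog
`mouseSd`, default 0.1) multiplies cell area to create the
between-animal correlation the statistics must absorb. The default
effect map emulates the progressive mutant phenotype: area ×1.2→1.8 and
jitter ×1.5→3.5 across ages, dropout ×4, against a flat control.
`simulateCellTable()` draws per-cell values from the same hierarchy
directly (group effect × mouse effect × cell noise, normal or lognormal)
without building images; it is the desk-scale path used for
thousand-replicate calibration and power studies, where tessellating
every replicate would add nothing but runtime.

What the generator does *not* emulate: real segmentation errors,
intensity/texture, mechanical correlations between neighboring cells
(it is not a vertex model), or the spatial structure of real damage.
Passing tests therefore validate the measurement and inference
machinery, not biological realism of the simulated sheets.

## Group comparison

All tests operate on the per-cell table with `mouse`, `genotype`, `age`
metadata.

* **Means.** `fitMeanComparison()` fits
  `metric ~ 0 + genotype + (1 | mouse)` by REML (lme4) and reports the
  marginal-mean difference with its standard error. Contrast p-values
  use *between-mouse* (containment) degrees of freedom,
  $n_{mice}-n_{groups}$: with hundreds of cells per animal, cell-level
  df would badly overstate the information content. A singular fit
  (mouse variance estimated at zero) degrades gracefully to the pooled
  covariance with a warning.
* **Spreads.** `fitVarianceComparison()` transforms each value to
  $|x - \mathrm{median}(\text{its group})|$ and runs the same mixed
  model on the residuals — a Brown–Forsythe-style robust dispersion
  test. Absolute residuals from the per-group median are the default
  (signed residuals would test location, not spread); `residual =
  "signed"` and `medianScope = "global"` expose the alternatives.
* **Multiplicity.** Each metric × contrast is assessed twice (raw and
  residual), so `bonferroniDunnAdjust()` doubles both p-values, capped
  at 1. `compareGroups()` runs the pair per age, adjusts, and marks
  significance as `*` (mean) / `#` (variance) at α = 0.05.
* **Many groups.** `tukeyPairwise()` fits one joint cell-means mixed
  model over the genotype × age cells and applies the studentized-range
  adjustment on containment df; with two groups it reduces exactly to
  the single contrast.
* **Trends.** `ageTrend()` regresses a per-mouse (or per-group) summary
  on age by OLS with a normal-approximation CI; the direction is the
  slope's sign only when the CI excludes zero.
* **Diagnostics.** `normalityDiagnostics()` returns per-group skewness,
  excess kurtosis (type-1 moment estimators) and q-q pairs.

### Validation sizes

The test suite calibrates the mean and variance tests on 1000 null
cohort replicates (2 groups × 4 mice × 500 cells, mouse sdlog 0.1, cell
CV 0.35): both hold 5% ± 2 points. Tukey's family-wise error is checked
on 500 replicates of 4 null groups. Power/recovery uses 100 seeds of a
1.5× mean effect and of a 2× SD effect (both detected in ≥90% of
seeds; the mean ratio is recovered with bias under 10%), and ten
image-level cohorts with age-increasing mutant jitter reproduce the
qualitative phenotype: lower mean hexagonality and a negative mutant age
trend. Raster-vector concordance is checked on a ~2100-cell sheet at
3 px/µm: per-cell areas within 2%, hexagonality within 0.3 score units,
mean interior neighbor count 6 ± 0.2. A companion regression test shows
why the hierarchy matters: an ordinary cell-level test on null cohorts
with strong mouse effects rejects far above nominal.

## Known limitations

* Scores are raw (unclamped) by default and can exceed the [0, 10]
  band marginally for pathological outlines; within-study comparisons
  are unaffected.
* The adjacency rule misses true Voronoi edges shorter than
  `minSharedPx` pixels (~1.5% of interior edges at default settings);
  these contacts are also the ones real membranes blur.
* Containment df is deliberately conservative; Satterthwaite-style
  approximations could be added where mouse counts are larger.
* The generator's disorder is positional only; it does not model
  cell-autonomous shape changes independent of packing.
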