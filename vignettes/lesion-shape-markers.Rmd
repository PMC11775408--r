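---
title: "Volume and shape markers of T2-hyperintense lesions across MRI resolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume and shape markers of T2-hyperintense lesions across MRI resolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

Glioma T2-hyperintense areas — nonenhancing tumor, edema and gliosis — grow
along white-matter tracts and develop complex, infiltrative shapes. How much
of that complexity a segmentation captures depends on the acquisition: a
high-resolution isotropic scan (0.75 mm voxels) resolves thin extensions and
fine surface texture that a clinical multislice protocol (e.g.
0.4 x 0.4 x 5 mm) blurs below the segmentation threshold. `glioshape`
quantifies binary 3D lesion masks with volume and convex-hull shape markers
and compares paired cohorts of high-resolution and clinical-resolution
segmentations of the same lesions. Because no patient data ship with the
package, a synthetic-lesion module generates paired cohorts whose degradation
physics reproduce the *direction* of resolution effects; it makes no claim to
reproduce any patient cohort's values.

# Markers

For a mask with foreground volume $V$ and (largest-component) surface area
$A$, and its convex hull with area $A_H$ and volume $V_H$:

* **Volume** (mL): voxel count x voxel volume over *all* connected
  components, on the native grid. Fragments of one lesion that appear
  disconnected at clinical resolution still count toward the total.
* **Convexity** $C = A_H / A$: 1 for convex bodies, decreasing with surface
  irregularity. For meshes of thin sheet- or capsule-like protrusions the
  ratio can exceed 1 (their meshed surface loses area under smoothing while
  the hull keeps their extent); such values are legitimate outputs, not
  errors.
* **Solidity** $S = V_{mesh} / V_H$: 1 for solid convex bodies, decreasing
  with concavity and with far-reaching extensions that inflate the hull.
* **Concavity index** $CI = 2 - (C + S)/2$: 1 at the convex limit, larger
  for more complex lesions. The source publications of this marker family do
  not print the formula; this composition is chosen so that the convex limit
  is exactly 1 and reported magnitudes (1.4-1.6 for glioma lesions) are
  attainable.
* **Fractal dimension** (box counting): about 2 for smooth surfaces, larger
  for rough ones; see below.

Shape is always measured on the largest 26-connected component (the rule used
when clinical masks fragment); total volume on all components.

# Geometry pipeline and its numerical choices

1. **Canonical masks.** Grids are cropped to the foreground bounding box and
   padded by one background voxel per face, so isosurfaces are closed and the
   padding rule is idempotent.
2. **Isotropic resampling by shape-based interpolation.** The signed
   Euclidean distance transform of the mask is resampled trilinearly to the
   analysis grid and thresholded at zero. Plain interpolation of the binary
   field turns 3-5 mm slice grids into terraced staircases whose spurious
   surface area and hull inflation dominate every shape marker; the distance
   transform reconstructs oblique and conical surfaces through thick slabs.
   A Gaussian regularisation of the resampled distance field
   (sigma per axis = max(0.5 x source spacing, 0.4 mm)) removes the residual
   slab kinks of each mask according to its own anisotropy, leaving
   fine-resolution detail untouched in fine-resolution masks. The default
   analysis spacing is the smallest axis spacing of the pair, floored at
   0.5 mm.
3. **Meshing.** Marching cubes on the binary field at level 0.5, with a
   constructive per-face chord rule (foreground-diagonal faces treated as
   connected, matching the 26-connectivity convention) so the mesh is
   watertight; triangle orientation follows the trilinear field gradient.
   Raw marching-cubes meshes of binary data overestimate smooth-surface area
   by roughly 9% (staircase normals), so meshes are Taubin-smoothed
   (lambda = 0.5, mu = -0.53, 10 iterations), which brings a digital
   sphere's area within about 1% of truth and a cube's within 4% without
   shrinking volume.
4. **Convex hull.** Quickhull over the mesh vertices (sub-voxel accuracy).
   Clouds above 4000 vertices are first reduced to their support points
   along 987 fixed Fibonacci-lattice directions; every support point is an
   exact hull vertex and at this angular density the replaced hull agrees
   with the full one far below marker tolerances.
5. **Box counting.** Counting boxes form a geometric ladder (factor
   $\sqrt2$) from one third of the surface's area-equivalent radius
   $r_{eq}=\sqrt{A/\pi}$ down to two analysis cells, and counts are averaged
   over four fixed fractional grid offsets. Three choices matter and were
   made for estimator consistency: scales *relative* to the object keep
   digital spheres of any size at FD 1.96-1.99 (absolute or dyadic scale
   sets make the fitted slope jump by 0.1 or more as scales enter or leave
   the window); the *area-equivalent* anchor is robust to thin protrusions
   that inflate the bounding box; and offset averaging suppresses
   lattice-resonance oscillations of the counts. A classic fixed-origin
   boundary-voxel counter (`fractal_dimension_voxel`, with a naive-counter
   test oracle) is kept for reference; on a perfectly axis-aligned cube any
   box-counting slope estimate is biased high at coarse scales (the
   boundary-shell count is $6m^2-12m+8$, convex in log-log), which is why
   the cube's plausible band extends to about 2.35 while smooth bodies stay
   within [1.9, 2.1].

# Statistics

Cohort comparisons use the paired Wilcoxon signed-rank test: zero
differences dropped, mid-ranks for ties, $W = \min(W^+, W^-)$. For up to 25
effective pairs the two-sided p-value is exact over all $2^n$ sign
assignments, computed by convolution of the doubled-rank generating
polynomial (identical to enumeration, and valid under ties, which
`stats::wilcox.test` does not provide exactly); beyond that, a normal
approximation with tie and continuity correction. Summaries are medians with
25th/75th percentiles (linear interpolation, type 7). Agreement is reported
as Bland-Altman mean difference with limits at $\pm 1.96$ sample SD. The
sensitivity analysis repeats everything after removing subjects below a
volume threshold (default 10 cm^3) in *either* condition, keeping the
paired design intact. Five markers are tested at alpha = 0.05 without
multiplicity correction, mirroring common practice for such descriptive
comparisons.

# The synthetic cohort: what it emulates

Each subject is a ground-truth lesion voxelized at fine spacing:

* a star-convex core of radius $R(1 + a\,(\min(B,1) - 0.5))$, where $B$ is a
  multi-scale spherical bump field (48 lobes, concentration
  $\kappa \sim \log U(8, 300)$, weight $\propto \kappa^{-0.35}$) — broad
  lobulation plus fine texture with a roughly self-affine spectrum;
* thin disc-shaped **sheets** (0.9-1.6 mm thick, radius 0.45-0.8 R)
  attached to the core — spread along white-matter tracts;
* optional thin capsule **tendrils** and a trans-midline **bridge** capsule
  (the structure that appears continuous at high resolution but vanishes or
  fragments on thick slices).

Observation model (`degrade_acquisition`): Gaussian point-spread blur
combined in quadrature with voxel box-averaging, sampling on the acquisition
grid with random phase and patient rotation (+-15 degrees), then
thresholding. Segmentation variability across scan sessions and raters is
modelled by a smooth random boundary-displacement field (SD 0.5-0.7 mm,
correlation 6-7 mm), a global threshold perturbation (SD 0.02-0.025) and
+-15% PSF variation. Without these sources the paired differences have
almost no variance and any nanometre-scale systematic bias drives the
paired test's type-I error toward 1; with them, the same mechanisms that
make real repeat segmentations disagree provide the noise floor.

Segmentation thresholds are *calibrated per acquisition*: bisection makes a
convex reference sphere of the cohort's size range volume-unbiased, and the
curve is interpolated at each lesion's equivalent-sphere radius. This
emulates raters who capture the true extent of simple lesions without bias,
while thin or textured structure below the point-spread scale is still lost
— the effect mechanism. No Rician image noise is simulated: the inputs are
expert segmentations, not raw images.

Two study scenarios are bundled:

* **default** — full size: $R \sim U(10, 25)$ mm, amplitude $U(0.4, 0.8)$,
  3-7 sheets, bridge probability 0.3, truth grid 0.4 mm, high-quality
  acquisition 0.75 mm isotropic (PSF 1 mm), clinical 0.4 x 0.4 x 5 mm (PSF
  0.8/0.8/6 mm), analysis spacing 0.5 mm. Used for the single-cohort
  comparison (n = 28) and the acceptance script.
* **replicate** — reduced size for replicate studies on one CPU:
  $R \sim U(9, 14)$ mm, clinical 0.5 x 0.5 x 3 mm (PSF 0.8/0.8/3.6), truth
  0.5 mm, analysis 0.7 mm, and additionally 2-6 thin tendrils whose loss at
  clinical resolution carries the volume effect at this scale. The **null**
  scenario is the replicate geometry with zero complexity (spheres), used to
  estimate the pipeline's type-I error. Replicate studies in the test suite
  use 20 effect and 30 null cohorts of 28 subjects; these cohort counts (and
  the reduced lesion sizes) are the package's study-size choices so the full
  suite runs in minutes.

What passing tests show — and what they do not: the synthetic cohorts
demonstrate that the pipeline recovers analytic geometry, controls false
positives on featureless lesions, and reproduces the *direction* of
resolution-dependent differences (larger volume, lower convexity/solidity,
higher concavity index and fractal dimension at high resolution) through a
plausible partial-volume mechanism. They do not certify behaviour on real
segmentations, whose complexity spectrum, rater behaviour and artefacts
(field inhomogeneity, registration, pathology heterogeneity) are outside the
simulator.

# Design decisions that were genuinely open

* **Connectivity** is 26-neighbour everywhere (maximal merging, consistent
  with treating visually continuous areas as one lesion).
* **Volume over all components vs largest only**: totals use all components
  so that fragmentation at clinical resolution does not spuriously shrink
  volume; shape uses the largest component only.
* **Solidity's numerator** is the smoothed-mesh enclosed volume (consistent
  sub-voxel geometry with the hull denominator), not the voxel count.
* **Ratio validity**: solidity must not exceed its hull bound beyond 10%
  slack (a true impossibility, so an error); convexity above 1 is possible
  for thin-structure meshes and is only rejected beyond gross inconsistency
  (1.5).
* **Marker grids**: whether shape should be computed on native anisotropic
  grids or after isotropic resampling is not settled in the marker
  literature; here everything is resampled, because meshing 3-5 mm slabs
  directly produces staircase artefacts that swamp the markers.
* **Exact vs approximate Wilcoxon**: exact (tie-safe) up to n = 25, which
  covers the n = 28 design after zero-difference drops in most cohorts;
  the approximation is continuity- and tie-corrected.

# Known limitations

* The generator's lesions are star-convex cores with attached primitives;
  real infiltrative growth produces topologically richer shapes (handles,
  cavities around resection sites) that are out of scope.
* Convexity of heavily tendrilled or sheeted shapes can exceed 1; the
  marker remains comparable between conditions but is no longer a pure
  "irregularity" scale there.
* The fractal dimension of smoothed meshes saturates near 2 for texture
  below the analysis scale; differences between conditions are meaningful,
  absolute values depend on the analysis spacing.
* Box-counting FD of perfectly axis-aligned solids (the cube fixture) is
  biased high at coarse scales; this is a property of the estimator class,
  not of the implementation.
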