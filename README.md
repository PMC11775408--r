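# glioshape

Quantifying how MRI resolution changes what we measure about glioma
T2-hyperintense areas.

## The problem

The T2-hyperintense area of a glioma — nonenhancing tumor plus edema and
gliosis — infiltrates along white-matter tracts. On a high-resolution
isotropic acquisition (0.75 mm voxels) a rater can trace thin extensions,
trans-callosal bridges and fine boundary texture; on a clinical multislice
protocol (0.4 × 0.4 × 5 mm or 0.4 × 0.5 × 3 mm) partial-volume averaging
pushes those structures below the segmentation threshold, so the delineated
lesion looks smaller, smoother and sometimes fragmented. `glioshape`
implements the quantitative side of that comparison for 3D binary lesion
masks:

* **per-lesion markers** — volume, surface area, and the convex-hull shape
  markers used for white-matter-hyperintensity morphometry:

  | marker | definition | convex limit |
  |---|---|---|
  | convexity | C = A_hull / A | 1 |
  | solidity | S = V / V_hull | 1 |
  | concavity index | CI = 2 − (C + S)/2 | 1 |
  | fractal dimension | box-counting slope of the boundary | ≈ 2 |

* **paired cohort statistics** — median (IQR) summaries per condition,
  exact paired Wilcoxon signed-rank tests, Bland–Altman agreement
  (mean difference ± 1.96 SD), and a ≥ 10 cm³ sensitivity re-analysis;

* **a synthetic-lesion study** — a generator of glioma-like ground-truth
  shapes (multi-scale surface texture, tract-following sheets, capsule
  tendrils, a trans-midline bridge) and an acquisition simulator
  (point-spread blur, anisotropic sampling, segmentation variability,
  volume-calibrated thresholds), so the whole pipeline can be exercised,
  calibrated and power-analysed without any patient data.

The geometry kernels (watertight marching cubes, Taubin smoothing, 3D
quickhull, signed Euclidean distance transform, box counting, 26-connected
labelling) are implemented in C++ via Rcpp; NIfTI input/output uses RNifti.

## Worked example

```r
library(glioshape)

# a 10 mm digital sphere on a 0.5 mm grid: markers at the convex limit
ball <- generate_lesion(lesion_spec(base_radius = 10, spike_amplitude = 0, seed = 3),
                        grid_spacing = 0.5)
compute_markers(ball, target_spacing = 0.5)
#> <shape_markers> V 4.175 mL (1 comp), C 0.998, S 0.995, CI 1.004, FD 1.964

# a textured lesion with tract-following sheets, observed twice
spec <- lesion_spec(base_radius = 10, spike_amplitude = 0.6, sheet_count = 3, seed = 11)
truth <- generate_lesion(spec, 0.5)
hq <- degrade_acquisition(truth, acquisition_spec(c(0.75, 0.75, 0.75), c(1, 1, 1),
                                                  segmentation_threshold = 0.47, seed = 1))
cl <- degrade_acquisition(truth, acquisition_spec(c(0.5, 0.5, 3.0), c(0.8, 0.8, 3.6),
                                                  segmentation_threshold = 0.47, seed = 2))
compute_markers(hq)
compute_markers(cl)
```

The high-resolution observation keeps the sheets and texture (larger volume
and hull, lower convexity/solidity, higher concavity index and fractal
dimension); the 3 mm-slice observation loses them.

The full cohort analysis is organised as numbered drivers:

```sh
Rscript analysis/01_simulate_cohort.R    # 28 paired NIfTI masks + manifest
Rscript analysis/02_compute_markers.R    # results/markers.csv (one row per mask)
Rscript analysis/03_compare_cohort.R     # comparison + sensitivity + Bland-Altman CSVs
Rscript analysis/04_replicate_studies.R  # power / type-I-error rate tables
```

A typical cohort-level report (step 03) looks like:

```
Paired cohort comparison (n = 28, alpha = 0.05)
  volume_ml          HQ  17.686 (8.929-34.880)  CL  17.404 (8.982-34.457)  p = 0.0702
  convexity          HQ   0.970 (0.939-0.991)   CL   1.018 (1.013-1.024)   p = 8.51e-06 *
  solidity           HQ   0.636 (0.610-0.681)   CL   0.857 (0.817-0.877)   p = 4e-06 *
  concavity_index    HQ   1.193 (1.176-1.221)   CL   1.061 (1.053-1.080)   p = 4e-06 *
  fractal_dimension  HQ   2.002 (1.993-2.015)   CL   1.971 (1.956-1.983)   p = 6.18e-06 *
```

(master seed 1) — the high-quality condition measures systematically less
convex, less solid, more concave and rougher lesions, with a small median
volume excess; exactly the direction expected when thin structure survives
only the high-resolution acquisition.

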