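Package: glioshape
Title: Volume and Shape Markers of Glioma T2 Hyperintense Areas Across MRI Resolutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional binary lesion segmentations of glioma
    T2 hyperintense areas with volume and convex-hull shape markers (convexity,
    solidity, concavity index, box-counting fractal dimension) and compares
    paired cohorts of high-resolution and clinical-resolution segmentations of
    the same lesions with nonparametric paired statistics (Wilcoxon signed-rank
    tests, Bland-Altman agreement). Includes a synthetic lesion generator and an
    acquisition-degradation simulator (partial-volume blur, anisotropic slice
    grids, segmentation variability) so the full pipeline can be exercised and
    calibrated without patient data. Geometry kernels (marching cubes,
    three-dimensional convex hull, signed Euclidean distance transform, box
    counting) are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
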