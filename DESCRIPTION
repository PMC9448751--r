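Package: flow4d
Title: Resolution-Sensitivity Analysis of 4D-Flow MRI Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the spatial resolution of 4D-Flow MRI
    acquisitions affects derived hemodynamic quantities. Provides an analytic
    pulsatile-flow ground truth (Womersley solution in a rigid straight tube),
    a virtual scanner that voxelizes the continuous field with partial-volume
    averaging and venc-scaled phase-contrast noise, threshold-based lumen
    segmentation with cross-sectional measurements, spatio-temporal inlet
    surface fitting, plane-level velocity and eight-sector wall shear stress
    metrics, and the cross-resolution comparison statistics (symmetric percent
    difference, mean and sample standard deviation summaries, and the exact
    Wilcoxon signed-rank test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
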