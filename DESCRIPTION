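Package: neuroprint
Title: Patient-Specific Brain Tumor Model Production: Seeded Graph-Cut
    Segmentation, Multiplanar QC and Printable Surface Export
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for producing patient-specific
    3D-printable brain tumor models from MR volumes: volume I/O
    (DICOM series, NIfTI) with denoising and resampling, interactive
    seed geometries (sketch, polygon, freedraw) rasterized to
    foreground/background seed sets, seeded binary segmentation by
    minimum s-t cut on a spacing-aware voxel graph (with region-growing
    and threshold fallbacks), multiplanar reconstruction with contour
    overlays for visual verification, overlap-resolved per-structure
    surface extraction to binary STL plus external mold generation,
    surgical-planning metrics (tumor depth categories, craniotomy
    size/location change scores) and the associated contingency
    statistics (Fisher's exact, chi-square). A synthetic phantom
    generator with ground-truth labels makes the whole pipeline
    testable without any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    tools,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
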