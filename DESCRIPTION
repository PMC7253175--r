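Package: osteoct
Title: Density-Tiered Micro-CT Morphometry of Maturing Cortical Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cortical bone maturation in micro-CT volumes of the
    long-bone metaphysis. Implements calibrated multi-level Otsu segmentation
    of bone into low-, mid- and high-mineral-density tiers (calcium
    hydroxyapatite scale), fraction-of-bone-length region-of-interest
    placement, whole-region and slice-by-slice density profiling, and 3D
    cortical porosity with per-pore volume, iso-surface area and open/closed
    classification. Ships a synthetic metaphyseal phantom generator with
    exact voxel-level ground truth so every stage of the pipeline can be
    validated without scanner data, plus repeated-measures group comparisons
    with Sidak-adjusted contrasts and slice-onset detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    emmeans,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
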