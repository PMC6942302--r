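Package: stemsect
Title: Function-Zone Segmentation and Vascular-Bundle Phenotyping of Stem
    Micro-CT Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for calibrated micro-computed-tomography
    (micro-CT) cross-section images of maize stems. Detects the three
    concentric function zones of a stem section (epidermis rind, dense
    periphery annulus, central inner/pith zone) as a hierarchy of closed
    contours, detects individual vascular bundles with zone-adaptive
    segmentation (fixed-threshold candidates refined by a region-based
    active contour in the inner zone; adaptive-mean segmentation with
    maximum-inscribed-circle object splitting in the periphery), and
    computes a five-category catalogue of intensity, geometry, distribution,
    layer and growth traits per bundle, per layer, per zone and per slice.
    Includes a synthetic cross-section phantom generator with full ground
    truth, exponential distance-size curve fitting, Voronoi growth-space
    statistics, equal-distance/equal-area layer partitions, and a documented
    JSON serialization (VBF) of all detected semantics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
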