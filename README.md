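# stemsect

Function-zone segmentation and vascular-bundle phenotyping for micro-CT
cross-sections of maize stems.

## What it does, and for whom

A transverse micro-CT slice of a maize internode has three concentric
tissue domains with very different image statistics: a bright epidermis
rind, a dense *periphery* annulus where small vascular bundles sit fused
in lignified matrix, and a dark *inner* (pith) zone with sparse, larger,
isolated bundles. `stemsect` is aimed at plant phenotyping researchers
who need per-bundle anatomy from such slices at scale. The pipeline:

1. **Zones** — recovers the domain geometry as three nested closed
   contours (slice outline, inner epidermis boundary, periphery/inner
   interface) via convexity-checked boundary repair, connectivity
   analysis of the pith cavity, local adaptive mean thresholding
   (31 × 31 window) and morphological cavity closing.
2. **Bundles** — detects bundles with a zone-adaptive strategy: in the
   inner zone, fixed-threshold candidates refined by a two-phase
   piecewise-constant active contour; in the periphery, adaptive-mean
   candidates screened against the exponential distance–size model

   `y = a − b·e^{c·x}`  (x = distance to the stem centre, mm),

   with oversized candidates split by greedy maximum-inscribed-circle
   decomposition (stop radius 3 px) and geodesic seed growth.
3. **Traits** — computes 28 traits in five categories: intensity (AI),
   dimensional geometry (W, H, MAL, MAW, CR, ICR, A, P, CHA),
   dimensionless shape (RA = A/(MAL·MAW), AR = MAW/MAL, CIR = 4πA/P²,
   ECC = √(MAL²−MAW²)/MAL, SPH = ICR/CR, CV = A/CHA), distribution (DC),
   equal-distance/equal-area concentric layers (AEL, NVBEL, AVBEL,
   VAVBEL) and per-zone growth traits (AEFZ, NVBPZ/NVBIZ, AVBPZ/AVBIZ,
   VAVPZ/VAVIZ, substance ratio, epidermis thickness), with clipped
   Voronoi cells as each bundle's exclusive growth space.

A fully annotated synthetic phantom generator drives validation, and all
detected semantics serialize to a documented JSON file (VBF).

## Worked example

```r
library(stemsect)

ph    <- generate_phantom(phantom_spec(seed = 7))   # synthetic slice + truth
zones <- detect_function_zones(ph$image)
det   <- detect_vascular_bundles(ph$image, zones)
det
#> <vb_detection> 380 bundles (150 inner, 230 periphery)

zt <- zone_growth_traits(zones, det, ph$image)
round(zt$AEFZ, 1)
#> epidermis periphery     inner
#>      42.1      63.0     261.3          # mm^2
round(c(zt$substance_ratio, zt$epidermis_thickness_mm), 3)
#> 0.358 0.639                            # ratio, mm

sch <- layer_partition(zones, 5, "EA", bundles = det$bundles, img = ph$image)
sch$layers
#>   layer  AEL NVBEL  AVBEL VAVBEL  AI
#> 1     1 65.3    39 0.1806  1.568 158
#> 2     2 64.8    41 0.1894  1.821 160
#> 3     3 64.8    32 0.1663  1.685 160
#> 4     4 64.7    38 0.1477  1.249 161
#> 5     5 64.8   230 0.0909  0.379 110

det$model
#> <distance_model> area: y = 0.1913 - 0.0004119 * exp(0.5666 x)  (n=380, sigma=0.02615)
```

The phantom carried 380 bundles and all 380 are recovered (noise-free
phantoms support exact count recovery). The equal-area layers have
near-identical areas (AEL); the jump of the bundle count in layer 5 and
the drop of the mean growth space (VAVBEL) reflect the dense periphery.
The fitted exponential shows bundle area decaying away from the centre.

Serialize and restore everything:

```r
tt  <- bundle_traits_table(det, zones, ph$image, sch)
doc <- vbf_document(zones, det, traits = tt, layers = sch)
serialize_vbf(doc, "slice.vbf.json")
doc2 <- deserialize_vbf("slice.vbf.json")   # every point and trait, exactly
```

A thin command-line wrapper ships in `inst/cli/stemsect.R`
(`synth`, `zones`, `detect`, `batch` subcommands).

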