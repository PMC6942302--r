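---
title: "Function zones, vascular bundles and the stemsect pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function zones, vascular bundles and the stemsect pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemsect)
```

## The problem

A transverse micro-CT slice of a maize stem internode shows three
concentric tissue domains with very different image statistics: a dense,
bright epidermis rind; a narrow *periphery* annulus in which many small
vascular bundles sit embedded in bright lignified matrix; and a large
*inner* (pith) zone where fewer, larger bundles lie isolated on
parenchyma that, in freeze-dried material, images at the air level.
No single threshold or object model works across these domains, so the
pipeline first recovers the domain geometry — three nested closed
contours — and then detects bundles with a method adapted to each zone.
From the detected objects it computes a five-category trait catalogue
(intensity, geometry, distribution, layer, growth) per bundle, per
concentric layer, per zone and per slice.

All coordinates are 0-based `(row, col)` pixels; physical traits are in
mm and mm² via the pixel size (default 0.01355 mm, i.e. 13.55 µm
micro-CT resolution; the synthetic phantoms use 0.04 mm, see below).

## Zone detection

Substance is any grey value strictly above the air level (threshold 0
after calibration, which maps the Hounsfield window [−1000, 9240]
linearly onto [0, 255] with clamping). The outer boundary (contour 1) is
the outer contour of the largest 8-connected substance component. Its
validity is judged by convexity: a stem section is nearly convex, so the
filled area must exceed 95 % of its convex hull's area. Broken rinds —
cracked samples — fail this test and are repaired by dilating with a
3×3 element until the outline becomes valid, then eroding the filled
region the same number of times.

The periphery/inner interface (contour 2) is the boundary of the largest
connected non-substance region strictly inside the slice
(4-connectivity, the digital dual of 8-connected substance); the
isolated inner bundles appear as holes of that cavity and are filled.

Between contours 1 and 2 the epidermis and periphery are separated by a
local adaptive mean threshold: a pixel is foreground iff it strictly
exceeds the mean of the in-zone pixels in the 31 × 31 window centred on
it. Two details of this step matter:

* The mean runs over *in-zone* pixels only. The zone image is extracted
  before segmentation, so pith air and outside-slice air (both grey 0)
  cannot drag the local mean down; including them produces a spurious
  foreground band along the inner boundary.
* The window (31 px) is chosen slightly wider than the epidermis so
  every window sees both rind and darker matrix; a strict inequality
  with zero offset leaves uniform regions empty.

Reversing this segmentation inside the slice leaves the periphery
cavities and the whole inner zone as foreground. Cavity components
smaller than 25 px are discarded — true inter-bundle cavities are far
larger, while under noise isolated sub-threshold pixels masquerade as
cavities and, once closed with a 15 px disc, would fuse across the rind.
Closing with the 15 px disc (the largest bundle diameter) then bridges
the cavities across the bundles; the outer boundary of the result is the
inner epidermis boundary (contour 3). Epidermis = between contours 1
and 3; periphery = between 3 and 2; inner = inside 2. The three masks
partition the filled slice region exactly, by construction.

## Bundle detection

**Inner zone.** A fixed threshold of 1 keeps every non-air pixel, which
deliberately over-segments: candidate components (8-connected, at least
5 px) carry all bundle boundary pixels but imprecise shapes. Each
candidate is refined by a region-based two-phase piecewise-constant
active contour: iterate (i) reassign every pixel of a window (twice the
candidate's bounding box) to the phase — inside/outside — whose mean
intensity is closer, (ii) one pass of 3 × 3 majority smoothing as a
morphological curvature regulariser. Fifty iterations are ample on these
small windows. Guards: a vanished contour returns the initialization
with a warning; a result outside 0.2–5 × the initial area is an error
(the detector then falls back to the unrefined candidate).

**Periphery zone.** Candidates come from the adaptive segmentation
restricted to the periphery mask. Because the bundles are densely packed
and fused with lignified tissue, a candidate may contain several
bundles. The tell-tale is size: dimensional traits of bundles decay with
distance x from the stem centre as `y = a − b·exp(c·x)`, so the detector
fits that model to the (distance, area) pairs of all candidates of the
slice (nonlinear least squares, deterministic initialization from the
data range and a log-linear pre-fit, robust residual scale
1.4826 × MAD) and flags candidates whose area exceeds the prediction by
more than 3 robust standard deviations. Flagged candidates are split:
maximal inscribed circles are extracted greedily from the Euclidean
distance transform until the radius falls below 3 px; circles closer
than the sum of their radii merge into seed groups; and every candidate
pixel joins the geodesically nearest group (seeded region growth inside
the candidate), conserving pixels exactly.

**Candidate verification.** Two noise guards are deliberate design
choices rather than paper constants. Components below 5 px are noise.
Additionally, a candidate whose maximum inscribed circle is below half
the 3 px splitting radius has no solid core: under heavy noise the
adaptive mean threshold produces ragged clusters that can pass an area
floor but essentially never contain a solid 3 × 3 core, while the
smallest genuine bundles do. Candidates truncated by the epidermis
boundary are exempt — an object that beat a rind-dominated local mean is
a strong detection even when its periphery-side fragment is thin.

## Traits

Dimensional measures treat a pixel as a unit square. Area A and convex
hull area CHA count pixel area (hull over the boundary pixels' corner
points); main-axis length/width MAL/MAW come from the minimum-area
rotated rectangle and the circumcircle radius CR from the minimum
enclosing circle, both over the corner points, so a 60 × 30 px rectangle
measures exactly 60 × 30; the inscribed radius ICR is the distance
transform maximum. The perimeter is the boundary chain length with the
Vossepoel–Smeulders step weights (0.948 axial, 1.340 diagonal) plus a
half-pixel rim offset of π: the raw 8-chain overestimates smooth
boundaries by ≈5 %, which would push the circularity of a digitized
disk down to ≈0.91, while the corrected estimate is unbiased and keeps
every dimensionless trait inside its theoretical range
(`CIR = 4πA/P² ≈ 0.99` for a radius-40 disk). The six dimensionless
traits are `RA = A/(MAL·MAW)`, `AR = MAW/MAL`, `CIR = 4πA/P²`,
`ECC = √(MAL²−MAW²)/MAL`, `SPH = ICR/CR`, `CV = A/CHA`.

Intensity (AI) averages non-zero grey values, consistent with the zone
histograms, which count grey 1..255 and exclude the dominant background
bin. Layer AI likewise uses all non-zero layer pixels, not only bundle
pixels.

**Layers.** The interior of contour 3 is divided into n = 5 concentric
layers by scaling contour 3 about the stem centre (the centroid of the
slice region): factors k/n give equal-distance (ED) rings, √(k/n)
equal-area (EA) rings — similarity scaling makes EA exact up to
rasterization (observed ≤ 1.02 max/min ratio). Bundles join the layer
containing their centroid.

**Growth space.** Each bundle's exclusive growth space is its Voronoi
cell clipped to the interior of contour 3. Cells are computed by
Euclidean nearest-centre labelling on the pixel raster, so the patches
partition the region exactly; the Delaunay-type neighbour graph is
exported as the adjacency dual of the patch labels. Per-zone and
per-layer means of the patch areas give the VAV* traits. 1-D k-means
with deterministic quantile initialization classifies bundle areas for
pseudo-colour rendering.

**Epidermis thickness** is not defined operationally in the field's
descriptions; here it is the mean, over 360 one-degree angular bins
around the stem centre, of the radial distance between contours 1 and 3.

## The phantom generator

Every stage is validated against synthetic cross-sections with exact
ground truth. The default phantom is a desk-scale section at 0.04 mm
pixels: outer radius 270 px (10.8 mm; slice ≈ 366 mm², close to the
339–349 mm² of field-grown material), epidermis 16 px (0.64 mm), inner
radius 228 px, 230 periphery + 150 inner bundles. The periphery bundle
area fraction is then ≈ 0.35, the realistic density for a periphery
annulus of ~40–55 mm² holding 300–400 bundles — and a load-bearing
choice: at this density the local mean sits ≈ 1.6 noise SDs above the
matrix even at noise SD 15, keeping false foreground rare.

Bundles are ellipses (axis ratio 0.65–1, random orientation) whose
equivalent radius follows `r(x) = 0.249 − 5.765·10⁻⁴ e^{0.502x}` mm
against centre distance x, with lognormal jitter (sdlog 0.12) and a
resolvability floor of 2.2 px. Placement is rejection sampling with
edge-to-edge clearance of at least 1 px, enforced exactly at pixel level
(no accidental fusions), so noise-free unfused phantoms support exact
count recovery. A configurable fraction of periphery bundles is placed
in deliberately touching clumps of 2–4 (major axes along the connection,
axis ratio 0.55–0.7, 15 % overlap) — fused candidates that the splitter
can resolve because the lobes stay above the 3 px circle radius — and a
fraction sits tangent to the rind. Tissue grey means follow the observed
histograms (epidermis 200, matrix 90, bundles 160, pith 0, background
0), realized as per-slice and per-bundle mean jitter of SD 10; bundles
within ~0.5 mm of the rind draw from a brighter distribution (mean 180),
mirroring the hypodermal lignification gradient. Air sits at
−2 × noise SD before Gaussian noise and clipping, emulating attenuation
at the calibration floor, so most air stays exactly at grey 0 as it does
in calibrated scans.

Batches scale the whole stem (radii and the size law) by
√(n_total/380): sparse slices are smaller stems with proportionally
smaller bundles. Above the base density the annulus widens slightly so
the packing fraction stays below the jamming limit of the rejection
sampler.

What the phantom does *not* emulate: beam hardening, ring artefacts,
partial-volume blur (a Gaussian point-spread option exists but is off by
default), non-elliptical bundle shapes, and the cellular texture of real
parenchyma. Passing phantom tests therefore demonstrates the geometric
and statistical correctness of the pipeline, not robustness to every
artefact of real scanners.

## Problem sizes and determinism

The validation suite runs phantoms between ~360 px (module tests,
120–200 bundles) and ~700 px (20-slice counting batches, 100–500 bundles
with noise SD 5–15 and fusion up to 10 %). Counting fidelity is scored
as the ordinary least-squares R² (free intercept) between true and
detected counts. Every stochastic component — generator, batches,
k-means — runs under explicit seeds and is bit-reproducible; all
tie-breaks (arg-max of the distance transform, label ordering) are
lexicographically fixed.

## Known limitations

* The adaptive mean threshold cannot find objects darker than their
  neighbourhood; bundles pressed against the rind rely on the
  lignification gradient being real (it is, in mature internodes).
* Noise can bridge bundles separated by a single pixel; such pairs are
  only recovered if their joint area trips the 3σ distance-model flag.
* The inscribed-circle splitter cannot resolve lobes whose inscribed
  radius is below the 3 px stop radius; at coarse pixel sizes small
  fused bundles stay merged.
* The distance-model fit assumes a decaying exponential; slices whose
  size profile deviates strongly (e.g. pathological sections) will
  mis-flag candidates.
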