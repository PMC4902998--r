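---
title: "Quantifying filamentous bacteria in bright-field micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filamentous bacteria in bright-field micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filatrace)
```

## The problem

Activated sludge settles poorly when filamentous bacteria outgrow the
floc-forming community (bulking and foaming). Monitoring them by manual
light microscopy is slow and subjective, and a submersible bright-field
microscope that images the suspension in situ cannot rely on staining,
phase contrast, dilution, or background-image subtraction. Everything has
to be done by morphology on noisy 8-bit frames: find the thin, elongated,
in-focus objects, ignore flocs, debris and everything out of focus, and
report a per-image total extended filament length (TEFL) whose trend an
operator can act on.

`filatrace` implements that pipeline, an ROC-based way to choose its three
thresholds, and a synthetic scene generator with exact ground truth so the
whole chain is testable without microscope data.

## The processing chain

Each frame passes through a fixed sequence:

1. **Bicubic downsampling** (factor 2, 1392 × 1040 → 696 × 520 px). The
   optics deliver about 0.5 µm of resolution, so the smallest filament
   diameter (0.8 µm) still spans ≈ 2.5 px after reduction; the bicubic
   kernel (Keys, a = −0.5, antialiased when shrinking) doubles as a mild
   low-pass filter.
2. **Gamma correction**, `g = f^0.6`, expanding the dark range where the
   faint transitions around thin objects live.
3. **Contrast enhancement.** In-focus objects are darker than the
   background; slightly defocused ones can be brighter, so both polarities
   matter. A high-boost stage adds the high-pass residual (image minus its
   3 × 3 mean; gain 1 by default) back to the image, then the grayscale
   top-hat (image − opening) is added and the bottom-hat (closing − image)
   subtracted, both with a diamond structuring element of radius 3. The
   result is clipped to [0, 1].
4. **Variance binarization.** The per-pixel population variance of the
   3 × 3 neighbourhood (reflect padding) is thresholded at a *fixed* value
   (default 10.5 × 10⁻⁴). Sharp transitions pass; strongly blurred
   out-of-focus structures do not. Because the threshold is fixed, the
   optically defined "virtual sample volume" is identical for every frame
   — the property that makes per-image counts comparable over months.
5. **Cleaning.** 8-connected components smaller than 77 px (the area of
   the smallest expected filament, 2.5 × 31 px) are removed; enclosed
   background holes with equivalent-area diameter `2*sqrt(A/pi)` below
   2.5 px are filled. Larger enclosed regions are deliberately left open:
   a curved filament can legitimately enclose background.
6. **Floc removal.** The exact Euclidean distance transform measures
   thickness; pixels at distance ≥ 6.4 px from the background are floc
   cores, which are dilated back by a disc of the same radius and
   subtracted from the mask. Erosion depth equals the threshold, so an
   equal-radius dilation is the natural reconstruction; both are
   configurable because thicker or thinner sludge may want another
   operating point.
7. **Skeletonization and spine pruning.** Remaining objects are thinned
   homotopically (Guo–Hall) to one-pixel-wide skeletons. For each
   skeleton, up to four candidate endpoints (the ones nearest each frame
   border, ties to the smaller row-major index) are examined; geodesic
   distances along the skeleton use the quasi-euclidean metric (1 per
   axial step, √2 per diagonal step). The pair with maximal geodesic
   separation are the strongest geodesic ends, and the spine is the set of
   pixels whose summed distance to the two ends equals their geodesic
   separation (the regional minimum of the sum map). Residual branches
   longer than 31 px — crossing filaments, typically — are reprocessed
   recursively by the same rule.
8. **RRG filtering and length conversion.** The reduced radius of
   gyration of each spine, `RRG = sqrt(M2x + M2y) / (Deq/2)` with
   `Deq = 2*sqrt(N/pi)`, is √2/2 for a disc and grows with elongation;
   spines with RRG ≥ 3.2 are accepted as filaments. Accepted geodesic
   lengths convert to µm by `length × 2 × 6.45 / 40` (downsampling factor
   × pixel pitch / magnification ≈ 0.3225 µm/px). Per image, TEFL is the
   sum; per batch, the online TEFL (oTEFL) is the mean of per-image TEFLs.

```{r example}
scene <- generate_scene(scene_spec(n_filaments = 3, n_flocs = 1, seed = 4))
cfg <- pipeline_config(resize_factor = 1)  # scene is at the analyzed scale
res <- process_image(scene$image, cfg, image_id = "demo")
length(res$records)
res$tefl_um
```

## Threshold selection

Three thresholds govern detection — variance (coarse: what counts as in
focus), distance (what counts as a floc) and RRG (what counts as
elongated). `roc_grid()` sweeps a grid of triples, runs the pipeline per
image, and pools pixel counts against a reference marking using a
displacement-tolerant match: true positives are reference pixels covered
by the disc-dilated detection, false positives are detections not covered
by the disc-dilated reference (radius 3 px by default — the tolerance for
the 1–2 px localisation slack between a drawn and a detected spine).

Because almost every pixel of a micrograph is background or non-filament
object, the usual `FP/N` would be misleadingly tiny; the false positive
rate is therefore normalized by the positives, `FPR = FP/P` (it can exceed
1), and specificity is `1 − FPR`. `convex_hull_points()` returns the
non-dominated upper-left frontier of the swept points, which is how the
default operating point (variance 10.5 × 10⁻⁴, distance 6.4, RRG 3.2) was
identified. Reference markings from several annotators combine by a
majority rule: `consensus_mask()` keeps pixels marked by at least three.

## The synthetic scenes

`generate_scene()` renders what the detector actually faces, with exact
ground truth: smooth bounded-curvature dark tubes 2.5–5 px wide and
31–620 px long (the expected 0.8–1.2 µm diameters and 10–200 µm lengths at
this scale), irregular floc blobs 15–60 px in radius, out-of-focus copies
blurred at σ ≥ 5 px with halved contrast and excluded from the truth
masks, and additive Gaussian sensor noise on a mid-gray background. The
spine of every in-focus filament is stored as the exact integer chain the
curve was rasterized from, with its quasi-euclidean length.

Two rendering choices matter more than they look:

* **Sensor noise defaults to σ = 0.005** (≈ 1.3 gray levels of an 8-bit
  camera). The fixed variance threshold presupposes a sensor whose
  enhanced noise floor lies below it; at σ = 0.01 the contrast-enhancement
  stage lifts background variance to ≈ 1.5 × 10⁻³, above any sensible
  threshold, and no fixed-threshold pipeline could work — on synthetic or
  real images alike.
* **Flocs carry grainy internal texture** (smoothed noise, s.d. 0.08,
  correlation 1.5 px). A uniform dark disc has no interior variance,
  binarizes as a hollow ring, and slips through the thickness filter;
  real aggregates are strongly textured, and the floc-removal stage
  depends on that.

What the scenes do **not** emulate: realistic point-spread optics,
uneven illumination, motion blur, overlapping filament bundles binarized
as one mass, and the density of a heavily bulking sludge. Passing the
synthetic recovery tests therefore shows the machinery is correct and the
operating point self-consistent — not that field performance on a
particular plant will match.

`scenario_suite()` fixes five scenes — isolated filaments, crossing
filaments, a filament touching a floc, high floc density, mixed focus —
and the acceptance script reports pooled detection rates, isolated-length
recovery, and batch oTEFL over them.

## Numerical and design choices

* **Variance input.** The variance transform is applied to the
  contrast-enhanced image, in flowchart order. The alternative (applying
  it to the un-enhanced gray values) fails on wide filaments: the interior
  of a 4–5 px uniform band is locally flat, so its body never passes the
  threshold, while the bottom-hat stage darkens the whole band and fixes
  exactly that. Population (n) rather than sample (n − 1) normalization;
  a flag switches it.
* **Threshold comparisons are inclusive** (≥) everywhere.
* **High-boost kernel.** The high-pass residual is taken against the
  3 × 3 mean with gain 1; kernel and gain are configurable since only the
  operation, not the kernel, is canonical.
* **Border handling** for all local filters is reflect padding.
* **Hole "diameter"** is the equivalent-area diameter `2*sqrt(A/pi)`.
* **Connectivity** is 8 for objects and skeletons, 4 for holes (the
  standard duality).
* **Spine tolerance.** Pixels belong to the spine when their summed
  geodesic distance is within ε = 10⁻⁶ × frame diagonal of the minimum —
  enough to absorb floating-point drift in the sum map, far below any
  real path difference (≥ 2 − √2 per detour step).
* **Closed loops** (skeletons without endpoints) are kept whole as their
  own spine with length equal to the loop perimeter; the endpoint-based
  rule is silent on them and discarding a looped filament would bias the
  TEFL downward.
* **The 4-candidate restriction** on endpoints is kept as specified for
  cost; it can in principle miss the true diameter on pathological shapes.
  The exhaustive all-pairs search exists in the test suite as an oracle
  and agrees with the restricted search on the tree-shaped skeletons the
  thinning stage produces.
* **RRG is computed on the pruned spine pixels**, not the filled object:
  after pruning, the spine is the object summary the filter must judge.
* **Floc reconstruction dilation** defaults to the distance threshold
  (the erosion depth); the structuring element is a disc, matching the
  isotropic thickness semantics of the distance transform.

## Known limitations

* At the default operating point, short filaments are structurally
  invisible: a straight spine must be ≈ 40 px (≈ 13 µm) long to reach
  RRG 3.2, so filaments near the 31 px minimum are rejected; curvature
  raises that bar further. This is the cost of suppressing floc-edge
  debris, and lowering the RRG threshold trades it back for false
  positives.
* Filaments that touch or cross flocs lose the overlapping pixels to the
  floc mask and may come back split into several shorter records.
* Closely spaced parallel filaments can binarize into one mass thick
  enough to be removed as a floc.
* The positives-normalized FPR is not a probability; comparisons with
  conventional ROC analyses must keep the denominator in mind.

## Problem sizes in the test suite

The tests run the geodesic machinery against an independent Dijkstra
oracle on 200 random skeletons of up to 60 px and the distance transform
against brute-force search on random masks up to 32 × 32; recovery tests
use the five 520 × 696 scenario scenes, and ROC-grid tests sweep reduced
grids on 200 × 280 scenes. These sizes exercise every code path while
keeping the default suite around half a minute on one core.
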