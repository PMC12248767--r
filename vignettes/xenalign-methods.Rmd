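---
title: "Keypoint identification between H&E and Xenium DAPI images: methods and design"
author: "xenalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keypoint identification between H&E and Xenium DAPI images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The registration problem

A Xenium run yields a DAPI-stained morphology image in instrument pixel
coordinates; the section is subsequently H&E stained and scanned on a
different device, so the histology image differs from the morphology image
in resolution, orientation and photometric polarity. Xenium Explorer
registers the two from a user-supplied set of matched keypoints (at least
three), fitting its own least-squares transform. `xenalign` automates the
generation of that keypoint set by finding nuclei visible in both images
and emitting their center coordinates.

The guiding assumptions are:

* the two images show the *same physical section*, so after undoing a
  gross orientation difference the residual transform is close to an
  anisotropic scaling (Explorer handles the fine transform);
* nuclei are the shared content: bright blobs in DAPI, dark blobs in H&E,
  and a nucleus segmentation of the H&E image renders them comparable to
  the DAPI signal;
* a correct match is supported by three independent kinds of evidence —
  local image similarity (PSNR over five shifted patches), global spatial
  topology (identical Delaunay edge structure), and local shape agreement
  (convex polygon overlap).

## Stage by stage

### Orientation search

Scanned H&E images arrive in any of the eight grid symmetries relative to
the instrument image (4 rotations × optional horizontal mirror). Because
MSE needs equal shapes, both images are resized to a square thumbnail
(`thumbnail_side`, default 512 px, bilinear) and the H&E image is first
inverted (`255 − luminance`) so that both modalities show bright nuclei on
a dark background; raw-luminance MSE would reward matching background, not
structure. All eight candidates are scored and the minimizer wins, with
ties broken toward the identity by scan order. The chosen orientation is
applied to the H&E image *and* to any supplied label image, so all
downstream coordinates live in the oriented H&E frame (the sidecar
manifest records the orientation so the original frame can be recovered).

The search is exhaustive over a discrete set, so the only failure mode is
a tissue whose thumbnail is nearly symmetric under one of the candidates;
the per-candidate MSE table is returned for inspection.

### Nucleus extraction

DAPI nuclei come from the instrument's boundary-polygon export
(`cell_id, vertex_x, vertex_y` in CSV or Parquet). H&E nuclei come from a
segmentation backend behind a single interface: `ground_truth` (a label
image supplied by the caller — what the test suite uses), `cellpose` or
`stardist` (thin adapters over the optional Python packages, raising a
dependency error with remediation when absent), or `custom` (any function
returning a label image). The fallback rule is a pure function of the
segment ratio — the number of recovered labels over the expected cell
count (taken from the DAPI nucleus count): strictly below 0.5 the
secondary backend runs, at or above 0.5 the primary stands. Default
backend settings follow common practice for these models (Cellpose:
minimum mask size 15 px, error threshold 0.8, one stain channel — the
green channel by default, since "channel 1" is ambiguous between 0- and
1-based counting; StarDist: probability threshold 0.3).

Every nucleus center, on both sides, is the midpoint of the boundary's
axis-aligned bounding box. This is deliberately *not* the centroid: it is
cheap, exactly reproducible from the stored boundary, and identical
between the two modalities' representations.

H&E nucleus polygons are convex hulls of the label's **pixel corner
points** (equivalently, the pixel-center hull dilated by half a pixel).
At desk scale nuclei are only a few pixels across, and a pixel-center
hull systematically underestimates the continuous outline by about half
a pixel of radius — enough to bias the overlap index down by several
percent; the corner hull is an unbiased outline and leaves the center
unchanged. Labels smaller than 3 pixels cannot form a polygon and are
dropped (counted and logged).

### Search regions and the five-direction PSNR consensus

An H&E center maps into DAPI coordinates proportionally to the image
dimensions; a square region of half-side `crop_radius_ratio ×
min(W_DAPI, L_DAPI)` around the mapped point collects candidate nuclei,
and regions with fewer than `extracted_region_min` (50) members are
rejected — too few candidates make a top-1 ranking meaningless.

Patches are cropped with half-side `crop_radius_pixel` (400 px full
scale) at the nucleus center and at four displaced centers
(±`center_move_pixel`, 300 px full scale, along each axis; "up" is
decreasing row index), then resized to 224 × 224. Crops that would cross
the image boundary reject the whole patch set rather than being padded —
padding would inject synthetic signal into the PSNR. The H&E side is the
segmentation rendered as a binary mask (nucleus 255, background 0); the
DAPI side is min–max stretched to [0, 255] per patch so both operands
share the `L = 255` scale. In the H&E frame the crop half-sides and move
distances are scaled by the per-axis dimension ratios so both patches
cover the same tissue extent before the common resize; without this, a
scale difference between the images would compare mismatched
neighborhoods.

Each candidate is scored in each direction around *its own* center with
the same radius/move scheme; the per-direction winner is the maximal
PSNR (+Inf, from identical patches, outranks all finite values; ties go
to the smallest candidate id for determinism). Only a candidate that
wins **all five** directions becomes an initial match — the displaced
patches widen the evidence beyond a single neighborhood, which is what
suppresses accidental single-patch winners. With `center_move_pixel = 0`
all five directions coincide and any winner is automatically a
consensus; the degenerate case is tested.

### Delaunay edge-consistency filtering

The epoch's matched centers are triangulated on each side with node ids
shared through the correspondence. While the two sorted edge sets
differ, the first mismatching edge in each list is located and the node
with the smaller first index among those two edges is removed from both
sides; both triangulations are rebuilt and the scan repeats. Each pass
removes exactly one node, so at most `n − 3` passes run. On termination
the two surviving triangulations are identical — asserted after every
run in the test suite — and re-filtering is a no-op.

Two design points deserve notice:

* **Edge comparison order.** Edges are normalized `i < j` and compared as
  lexicographically sorted lists; when one list is a prefix of the other,
  the first extra edge is the trigger. This is the deterministic reading
  of index-ordered comparison.
* **Sensitivity is index-biased.** The removal rule deletes the *smaller
  first index* of the trigger edges, so inconsistencies around a
  high-index outlier are often resolved by consuming its lower-index
  neighbors first; occasionally the graphs reach consistency with the
  outlier still present. Measured on random 20-point correspondence sets
  with one point displaced by 5× the median nearest-neighbor spacing,
  the displaced point is removed in roughly 75–90% of trials depending
  on seed and displacement direction (displacements that leave a hull
  vertex's topology unchanged are invisible to any purely topological
  filter). The filter is therefore best understood as an *edge-set
  equalizer* with good but not guaranteed outlier targeting; the polygon
  stage and the five-direction consensus carry the rest of the burden.
  The triangulation itself is an in-package Bowyer–Watson construction
  (no suitable triangulation package is among the declared
  dependencies), cross-checked in the tests against a brute-force
  empty-circumcircle enumeration; cocircular ties resolve
  deterministically by the strict in-circle predicate, and the
  super-triangle sits 10^5 × the data extent away so hull slivers with
  huge circumcircles triangulate correctly.

### Polygon overlap filtering

Surviving pairs compare shapes: the H&E hull is scaled by the per-axis
dimension ratios into DAPI units (configurable; identity scale available
for data whose native resolutions already agree), both polygons are
translated so their bounding-box midpoints — the keypoints themselves —
sit at the origin, and the convex intersection is computed by
Sutherland–Hodgman clipping (vertices deduplicated at 1e−9; implemented
in-package as no polygon-clipping package is among the declared
dependencies, and validated against a Monte-Carlo rasterization oracle).
With intersection area `I` and polygon areas `S` (H&E) and `T` (DAPI),
the average index `(I/S + I/T)/2` is thresholded at 0.9, or the stricter
minimum index `min(I/S, I/T)` at 0.92; pairs *below* the threshold are
removed. Since `min ≤ avg` always, every pair kept at minimum-0.92 also
passes average-0.92. Degenerate hulls (collinear boundaries) drop the
pair with a warning rather than failing the run.

### Epoch loop and output

Each epoch samples `cell_num_each_epoch` (100) H&E nuclei uniformly
without replacement from the not-yet-sampled pool, runs the three stages
on that epoch's matches (filters run per epoch, not on the accumulated
set; an optional global Delaunay pass over the accumulated set exists
behind `global_graph_pass`, default off), and adds survivors to the
accumulated set under two rules: exact duplicates are dropped, and a
nucleus already matched to a different partner rejects the new pair
(one-to-one enforcement — duplicate anchors are geometrically degenerate
for a landmark fit). The loop stops at `keypoints_min` (15; 10 in the
FFPE preset) keypoints, pool exhaustion, or `max_epochs` (100). Fewer
than three final keypoints is a hard error with the per-stage skip
counts in the message; between three and the minimum is a success with a
warning. Empty epochs count toward the epoch number and are logged.

The output CSV has header `fixedX,fixedY,alignmentX,alignmentY` — fixed
= DAPI, alignment = oriented H&E, full-resolution pixels, written with
17 significant digits, LF endings — and a JSON manifest records both
image dimensions, the applied orientation and the full configuration.
With a fixed `rng_seed` and fixed inputs two runs are byte-identical.

## The synthetic scene generator

`generate_scene()` plants elliptical nuclei (uniform semi-axes within
`nucleus_radius_range`, uniform orientation) on a jittered grid, which
enforces the minimum center spacing by construction; requesting more
nuclei than the grid holds is a generation error. The scene is defined
in the DAPI frame and rendered twice: DAPI as bright ellipses (intensity
200 on background 10) plus additive Gaussian noise (sd 8 by default,
clipped to [0, 255]); H&E as dark purple ellipses on a light background
in a frame scaled down by `scale`, then transformed by the planted
orientation. Because the H&E mask is rasterized by mapping each H&E
pixel center through the same proportional transform the pipeline uses,
the correspondence between the two renderings is exact, and
`planted_transform()` returns the closed-form map used to score emitted
keypoints.

What the generator does *not* emulate: staining variability, tissue
folds, out-of-focus regions, nucleus shape irregularity, densely
touching nuclei, or segmentation errors (the ground-truth backend is
perfect by construction). Passing tests on these scenes therefore
demonstrates the correctness of the pipeline's geometry, scoring and
filtering logic — not robustness to real-world image degradation, which
depends on the chosen segmentation backend.

Default scene conditions: 300 nuclei in a 600 × 900 px DAPI frame,
semi-axes 5–9 px, center spacing ≥ 26 px, noise sd 8, H&E at 1/1.5
scale. The end-to-end verification scene uses 500 nuclei at 840 × 1260
px (spacing ≥ 32 px, semi-axes 6–10 px) with a planted 180° rotation.

## Parameters at desk scale

The full-scale defaults (`crop_radius_pixel` 400, `center_move_pixel`
300, region ratio 0.125 with ≥ 50 cells) are calibrated for instrument
images tens of thousands of pixels across with 10^4–10^5 nuclei. The
synthetic scenes are ~100× smaller in area, so the test and acceptance
configurations shrink the patch geometry proportionally (radius 48 px,
move 36 px — preserving the 4:3 radius:move ratio) and use the 0.5
region ratio, which is the preset used in practice when a 0.125-ratio
region cannot hold 50 cells. These sizes keep the whole suite at
minutes-scale on one CPU; they are scene-size adaptations, not changes
to the method.

Numerical choices collected in one place: 8-bit normalization
everywhere (`L = 255`; deeper DAPI planes are min–max stretched at
load); bilinear interpolation for all resizing; crop windows are
half-open `[c − r, c + r)` around the rounded center (even side, no
off-by-one asymmetry); argmax ties break to the smallest candidate id;
clip vertices deduplicate at 1e−9; hull orientation is normalized to
positive shoelace area.

## Known limitations

* The Delaunay filter's index bias (above) means a residual wrong match
  can survive topological filtering; in practice it must then also beat
  the 5-direction consensus and the polygon overlap, which the decoy
  experiments show is rare.
* PSNR compares a binary mask with a stretched intensity patch; tissues
  whose DAPI background structure dominates (autofluorescence, debris)
  weaken the ranking. The practical remedy — larger patches and wider
  search regions via the presets — is exposed in the configuration.
* The orientation search assumes one global grid symmetry; slides
  scanned at an oblique angle fall outside the candidate set and would
  need manual pre-rotation.
* JPEG input is not supported (no JPEG reader among the declared
  dependencies); convert to TIFF or PNG.
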