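# xenalign

Automatic keypoint identification for aligning H&E histology images with
10x Genomics Xenium DAPI-stained morphology images.

## The problem

Xenium spatial transcriptomics runs produce a DAPI morphology image (bright
nuclei on a dark background); the same section is then H&E stained and
scanned (dark nuclei on a light background). Cross-referencing transcripts
with histology requires registering the two images, which Xenium Explorer
does from a set of matched landmark points — at least three keypoints, each
naming the same nucleus in both images. Placing those landmarks by hand
takes a domain expert hours per sample. `xenalign` finds them
automatically and writes the keypoint alignment CSV that Xenium Explorer
imports.

## The method

For images `a`, `b` of equal size `M x N` with maximum intensity `L`:

    MSE(a, b)  = (1 / MN) * sum_ij (a_ij - b_ij)^2
    PSNR(a, b) = 10 * log10(L^2 / MSE(a, b))

The pipeline has five stages:

1. **Image processing.** The H&E image is auto-oriented against the DAPI
   layout by minimising thumbnail MSE over the eight discrete grid
   symmetries (4 rotations x optional mirror). H&E nuclei come from a
   segmentation backend (Cellpose or StarDist adapters, a ground-truth
   label image, or any custom function; a segment ratio below 50% of the
   expected cell count triggers the fallback backend). DAPI nuclei come
   from the instrument's nucleus boundary export. Every nucleus center is
   the midpoint of its boundary's bounding box.
2. **Multi-directional PSNR assessment.** Each sampled H&E nucleus center
   is mapped into DAPI coordinates proportionally to the image dimensions
   (`X_DAPI = W_DAPI * X_HE / W_HE`, likewise for Y), and a square search
   region (half-side = ratio x the smaller DAPI dimension, kept only when
   it holds >= 50 nuclei) supplies candidate partners. Five patches —
   center, up, down, left, right — are cropped around each nucleus,
   resized to 224 x 224, and scored by PSNR between the binary H&E
   segmentation rendering and the contrast-stretched DAPI patch. A
   candidate that ranks top-1 in **all five** directions becomes an
   initial match.
3. **Delaunay triangulation graph matching.** The matched centers on each
   side are triangulated; while the two edge sets differ, the node with
   the smaller first index of the first mismatching edges is removed and
   both graphs rebuilt. This enforces identical neighborhood topology.
4. **Nucleus polygon matching.** Each surviving pair's convex-hull
   polygons are scaled into a shared frame and centered; the pair is kept
   only if the overlap index — `(I/S + I/T)/2` (average mode, threshold
   0.9) or `min(I/S, I/T)` (minimum mode, threshold 0.92), with `I` the
   intersection area and `S`, `T` the polygon areas — reaches the
   threshold.
5. **Keypoint file generation.** Accumulation proceeds epoch by epoch (100
   sampled H&E nuclei per epoch, without replacement) until the configured
   minimum (15 by default; 10 for the FFPE preset) is reached, then the
   pairs are written as `fixedX,fixedY,alignmentX,alignmentY` (fixed =
   DAPI, alignment = H&E) with a JSON sidecar manifest.

A synthetic paired-scene generator (elliptical nuclei rendered in both
modalities under a known orientation and scale, with boundary exports,
ground-truth labels and the planted correspondence table) makes the whole
pipeline testable without instrument data.

## Worked example

```r
library(xenalign)

scene <- generate_scene(scene_spec(
  n_nuclei = 300, dapi_dims = c(600, 900), scale = 1.5,
  orientation = orientation_code(180), seed = 11))

cfg <- pipeline_config(crop_radius_ratio = 0.5, crop_radius_pixel = 48,
                       center_move_pixel = 36, rng_seed = 5)

res <- run_pipeline(cfg, list(he_rgb = scene$he_rgb, dapi = scene$dapi,
                              boundaries = scene$boundaries,
                              label_image = scene$label_image),
                    out_csv = "keypoints.csv")
res$orientation
#> <orientation 180 degrees>
res$report
#> <run_report: 68 keypoints in 1 epoch(s) [68]>
head(res$pairs, 3)
#>   he_id          dapi_id   fixedX   fixedY alignmentX alignmentY
#> 1   185 synthcell-0185-1 158.9051 158.4761        106      105.5
#> 2   297 synthcell-0297-1 221.9666 378.6026        148      252.5
#> 3   213 synthcell-0213-1 160.5922 657.3539        107      438.0
```

The planted 180-degree orientation is recovered, one epoch of 100 sampled
nuclei already yields 68 keypoints (well past the minimum of 15), and each
row pairs a DAPI nucleus center (`fixedX/Y`, DAPI pixels) with the same
nucleus's center in the oriented H&E image (`alignmentX/Y`, H&E pixels).
`keypoints.csv` is ready for Xenium Explorer's "use an existing alignment
file" import; `keypoints.csv.manifest.json` records image dimensions, the
applied orientation and the configuration.

The same pipeline is available from a shell:

```sh
Rscript inst/scripts/xenalign simulate --out-dir scene --seed 11 --n-nuclei 300
Rscript inst/scripts/xenalign run --he scene/he_image.png --dapi scene/morphology.tif \
    --boundaries scene/nucleus_boundaries.csv --labels scene/he_labels.tif \
    --config cfg.yaml --out keypoints.csv
Rscript inst/scripts/xenalign validate keypoints.csv
```

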