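---
title: "Methods: filtering, detecting and evaluating birds in aerial open-water imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, detecting and evaluating birds in aerial open-water imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skyfilter)
```

# The processing problem

Aerial marine-bird surveys photograph open water from low altitude with
large-format frame cameras (the frame geometry used throughout this
package is 10328 x 7768 pixels). Ground sample distance varies with
altitude, roughly 0.14-1.5 cm per pixel, so a 40 cm sea duck spans
anything from ~27 to ~285 pixels. Most frames are empty water; the frames
that matter contain small dark targets on a bright, textured background
broken by saturated glare. `skyfilter` implements the three-stage
workflow this situation calls for — filter frames by occupancy, detect
individual birds on the kept frames, leave a classification slot — along
with the tiling, annotation-refinement and evaluation machinery around
it. This vignette records how each piece works, the parameters that
matter, and the design decisions taken where more than one construction
was defensible.

# Tiling large frames

Frames are too large to process whole, so they are decomposed by a
sliding window: training uses 720-pixel windows with a 540-pixel stride;
evaluation uses 1440-pixel windows with a 1080-pixel stride, each patch
rescaled to 960 pixels before prediction to cut compute. Windows start at
multiples of the stride and the final window on each axis is *clamped* to
the frame border. Clamping was chosen over padding (which invents pixels)
and over dropping partial windows (which loses coverage): with clamping
every frame pixel belongs to at least one tile, and the tile count per
axis is the closed form `ceiling((parent - window)/stride) + 1` — 19 x 15
= 285 training tiles for a full frame. A bird that straddles two
overlapping tiles is deliberately duplicated at training time (each tile
is treated as an independent example) and deduplicated at inference by
greedy non-maximum suppression (NMS) after detections are mapped back to
parent coordinates. NMS sorts by score and keeps a box iff its IoU with
every kept box is below the threshold (default 0.5, configurable — the
workflow only requires that "significant" overlap be suppressed); ties
break by score, then `x0`, then `y0`, so results are deterministic.

Boxes are stored internally as half-open real rectangles
`[x0, x1) x [y0, y1)` in 0-based pixel coordinates. The half-open
convention makes areas and IoU exact integer arithmetic on integer boxes
and avoids the +/-1 ambiguities of closed boxes; conversion to the COCO
`[x, y, w, h]` convention happens only in the readers/writers.

# Stage 1: occupancy filtering

Each evaluation patch receives a bird-occurrence probability; the parent
frame's probability is the **maximum** over its patches, and the frame is
kept iff that maximum exceeds the decision threshold (default 0.5 — no
principled prior value exists, so it is exposed in the configuration).
Thresholding the maximum is exactly the any-patch rule ("if any patch
contains a bird, the frame does"), but retains a continuous score per
frame for ROC-style analysis. Dropped frames are never deleted: the
probability table lists every frame, and the run record names every
dropped frame that contained ground truth, because false-negative drops
propagate directly into population-estimate bias.

Two classifier backends exist. `proposal_heuristic` needs no training: a
patch scores by its blob-proposal count (exactly 0 with no proposals).
`small_cnn` is a compact convolutional classifier built for CPU training
in seconds: one convolutional layer of *fixed* band-pass kernels
(difference-of-Gaussians at sigma pairs 1/2, 2/4, 3/6, and four oriented
Gaussian first-derivative kernels at sigma 1.5), squared-ReLU activations
of both response signs (14 maps), global average pooling (GAP), and a
single fully connected logistic layer fit as a ridge-penalized GLM
(lambda 1e-3). Only the final layer is learned, so training is convex and
deterministic. The GAP + FC structure is not incidental: it is what makes
a class-activation map (CAM) available — the response maps weighted by
the class weights — which the box refiner can use as its localization
backend. Patches larger than the native 480-pixel input are scanned with
a half-overlapping 480-pixel window and max-pooled, so a 960-pixel
evaluation patch is seen at the same object scale the classifier was
trained at (1440-to-960 rescale and 720-to-480 training crops share the
2/3 factor).

Training patches follow the standard random-resized-crop recipe: crop
area 0.08-1.0 of the source patch, aspect jitter in [3/4, 4/3], resize to
480 x 480, horizontal flip with probability 0.5. A crop is labeled
positive iff it contains at least one ground-truth box *center*; the
center rule avoids double-counting birds cut by crop borders. When the
aspect-jittered crop does not fit the source, the full patch is used, so
a degenerate area range of (1, 1) is a pure resize.

# Stage 2: the blob + HOG + SVM detector

The detector is deliberately classical. The chain: contrast enhancement,
global threshold at 0.9, dilation with a 12 x 12 square structuring
element, 8-connected component labeling, one proposal per component,
HOG features, linear SVM score.

Choices that needed making:

- **Contrast enhancement** (`stretch` default): a white-point stretch —
  divide by the 99.9th intensity percentile. Sunlit water sits near
  saturation, so this normalization puts the water surface just below 1.0
  regardless of scene content, and the fixed 0.9 threshold then separates
  dark targets from background on occupied *and empty* frames alike. A
  percentile stretch anchored at both ends (e.g. 2-98%) was rejected: on
  a water-only frame it amplifies sensor-scale noise across the full
  range and the fixed threshold fires everywhere. CLAHE is available as
  an option.
- **Polarity**: with `dark_fg` (default; dark ducks on bright water) the
  foreground is every pixel *below* the threshold after enhancement;
  `bright_fg` mirrors it.
- **Dilation** is read as one pass with a square element whose side is
  the dilation factor (even sizes extend one pixel further right/down of
  the origin). Its purpose is fusing a bird fragmented by specular
  highlights into one blob; its side effect is merging two genuinely
  distinct birds closer than the factor, the residual miss mode of the
  detector.
- **Proposal geometry**: components are labeled on the *dilated* mask
  (8-connectivity), but each proposal box is tightened back to the
  pre-dilation foreground pixels of its component, and the minimum-area
  filter (`min_blob_px`, default 4) counts those evidence pixels. Without
  tightening every box would be inflated by the dilation radius and high-
  IoU evaluation would be meaningless.
- **HOG**: 64 x 64 window, 8 x 8 cells, 2 x 2-cell blocks stepped one
  cell, 9 unsigned orientation bins, L2-Hys block normalization (clip
  0.2) — the standard pedestrian-HOG geometry, fully configurable; the
  descriptor length is `7*7*4*9 = 1764`. Gradient magnitude votes are
  linearly interpolated between neighboring orientation bins; spatial
  assignment to cells is hard. A constant crop yields the zero vector.
- **SVM**: linear kernel (nothing in this feature space calls for more),
  cost 1. Scores for ranking and NMS are the logistic of the decision
  value, giving comparable values in (0, 1); proposals below 0.5 are
  dropped by default. A proposal is a positive training example iff its
  best IoU against an annotation box reaches 0.5 — the same convention
  the evaluation uses for true positives. If a training corpus produces
  proposals of only one class (immaculate water: all positive;
  hopelessly loose annotations: all negative), the SVM cannot be fit and
  the high-level trainer falls back, with a warning, to the constant
  classifier that accepts or rejects everything — an honest description
  of what such a corpus supports.

# Bootstrap annotation refinement

Hand-drawn boxes are loose; training on them depresses localization
quality at high IoU. The refiner tightens each box: crop the box plus a
context margin (default 0.2 of box size per side), compute an activation
map, initialize a mask by Otsu's threshold on the map, evolve a two-phase
morphological level set, keep the largest 8-connected component, and
return its tight bounding box.

The activation map has two backends. `contrast` (default, model-free):
absolute deviation from the crop's robust background level — the median
of its border pixels — min-max normalized; deviations whose maximum is
below 0.1 are treated as noise and return a zero map, so water-only crops
fall through to the fallback rather than amplifying sensor noise. `cam`
uses the occupancy classifier's class-activation map.

The level set is a discrete Chan-Vese-type two-phase evolution built from
morphological operators: each iteration applies one binary 3 x 3 majority
smoothing (the curvature term), then reassigns the pixels of the narrow
band around the front to whichever phase mean (`c1` inside, `c0`
outside) is closer in squared heat distance — the descent step on the
two-phase variance energy. Smoothing-before-data ordering makes any shape
fully supported by the heat map an exact fixed point of one iteration.
Evolution stops at the iteration cap (default 100) or once the mask is
unchanged for 3 consecutive iterations. Degenerate situations — empty or
all-foreground initialization, phase means closer than 1e-6, final
foreground under 4 pixels, or no stabilization within the cap — return
the original box flagged `converged = FALSE`; a refined box therefore
never silently replaces its input on weak evidence, and never extends
beyond the loose box plus margin.

Refinement is single-pass. An "iterative bootstrap" in the sense of
alternating refine and retrain rounds can be built on top by feeding the
refined annotation set back through the pipeline driver; the refiner
itself is close to idempotent on its own output, which the tests check.

# Evaluation

All metrics are computed from first principles. Matching at an IoU
threshold processes detections in descending score order; each claims the
unmatched ground-truth box of highest IoU if that IoU reaches the
threshold, ties breaking toward the lower ground-truth index; each ground
truth matches at most once. Average precision interpolates precision as
`p(r) = max` precision at any recall `>= r` and averages over the
101-point recall grid 0, 0.01, ..., 1. The defining sum of AP over the
recall grid is normalized by 1/101, the convention under which all
reported AP values lie in [0, 1]. Detections are pooled across images
into one ranked list per threshold (per-image averaging is not the
default, matching common benchmark practice). The report carries AP at
each threshold of the grid 0.50:0.05:0.95, their mean (mAP), the 0.50 and
0.75 entries (mAP50, mAP75), and AR — defined here as the mean over that
same grid of the recall achieved by the full ranked list, with no
max-detection cap. Undefined quantities (no ground truth; zero
denominators in image-level precision/recall) are flagged `NA`, never
silently zero.

GSD stratification partitions images into `< 0.6`, `0.6-1.2` and
`> 1.2` cm bins; both edges belong to the middle bin. Empty strata
produce empty (undefined) reports rather than errors.

The test suite holds the implementation to two independent oracles: a
brute-force matching-and-sweep written as plain loops (agreement to
1e-9) and a separately coded port of the COCO benchmark's accumulation
algorithm — precision envelope by reverse running maximum, sampled at
101 recall thresholds (agreement within 0.01). Connected-component
labeling is checked against a flood fill, and IoU against direct area
arithmetic on exhaustive small integer boxes.

# The synthetic scene generator

Every quantitative claim in the tests is made against scenes with exact
ground truth. A scene is bright water (base intensity 0.97) plus
band-limited wave texture — coarse Gaussian noise bilinearly upsampled at
two spatial scales — whose amplitude is 0.04 x `sea_state`, plus glare:
a low-frequency field thresholded at its `(1 - glare_fraction)` quantile
and set to saturation, so the saturated-pixel fraction tracks
`glare_fraction`. Birds are flat-shaded ellipses with major axis
`bird_length_cm / gsd_cm` (floor 2 px), axis ratio uniform in
[0.35, 0.65], uniform orientation, intensity `background mean -
bird_contrast` (polarity configurable), and per-pixel Gaussian jitter
(sd 0.015). Placement rejection-samples up to 50 tries per bird so that
no two ground-truth boxes exceed IoU 0.1, then drops the bird; the
ground truth reflects what was actually placed. The box diagonal of a
rotated ellipse is exactly `L * sqrt(1 + ratio^2)` regardless of
orientation, which the tests exploit as the footprint law.

Defaults encode the study conditions the package is exercised under: a
40 cm body length (a sea-duck-scale stand-in — target pixel extents are
not published for the source surveys, so the value is configurable and
not load-bearing), contrast 0.5, `sea_state` 0.2 and no glare for the
"easy" regime, versus `sea_state` 1 with 10% glare for the "hard" regime
used as the contrasting acquisition condition in cross-regime tests. At
`sea_state` 1 the dark tail of the wave texture crosses the detector's
threshold and produces genuine clutter blobs, which is what gives the
SVM negatives worth learning.

What the generator does **not** emulate: plumage and shape detail (birds
are contrast blobs, which is all the classical detector uses), wakes and
foam, sun-angle-dependent glare geometry, sensor noise correlated with
the camera's color processing, and overlap between consecutive frames.
Passing tests therefore certify the pipeline's mechanics and its
qualitative behaviors (refinement helps; detection degrades with coarser
GSD; filtering is near-lossless on clean scenes) — not field performance
on survey imagery, where backbone capacity and training-data breadth
dominate.

# Problem sizes and runtime posture

The shipped tests and the acceptance script run everything at desk
scale, chosen so the full suite completes in a few minutes of one CPU:
512-1152-pixel scenes standing in for parent frames, 4-6 birds per
occupied scene (densities at which the dilation-merge miss mode stays
rare, as it is in real surveys where rafting birds are the exception at
these footprints), tens of scenes per experiment, and the deterministic
seeds recorded in each test. The pipeline itself has no scale
assumptions beyond memory: the tiler exists precisely so full
80-megapixel frames stream through in 285 windows.

# Known limitations

- Two birds closer than the dilation factor merge into one proposal and
  at most one can be recovered; the SVM typically rejects the merged
  blob, trading the false positive for two misses.
- The `small_cnn` filter learns only its final layer over a fixed filter
  bank; it is a workflow-scale stand-in with the same interface and CAM
  structure as a deep backbone, not a competitive image classifier. The
  backend seam accepts any stronger model.
- Stage 3 is a labeled stub by design; species classification is out of
  scope.
- The evaluation pools detections across images; per-image AP averaging,
  confidence intervals, and mask metrics are not provided.
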