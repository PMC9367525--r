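---
title: "Quantifying CAM angiogenesis: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CAM angiogenesis: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The chick chorioallantoic membrane (CAM) is a densely vascularized
extra-embryonic membrane used as an in vivo assay for tumor-induced
angiogenesis: a tumor graft recruits host vessels, and the response is read
out from microscopy images of the membrane and from laser speckle contrast
imaging (LSCI) perfusion maps. `vascam` implements the full quantification
chain for the in ovo variant of this assay:

1. a trainable encoder--decoder that scores every pixel of an RGB
   microscopy image for membership in the blood-vessel class;
2. skeleton-based morphometry of the thresholded mask, yielding the four
   assay readouts -- total vessel area (px^2), total vessel length (px),
   mean vessel thickness (px) and number of branching points;
3. an LSCI-style perfusion summary -- stable-frame selection and
   averaging, a perfusion-unit (PU) band filter, and the mean blood flow
   (mean PU over perfused pixels x perfused area in mm^2);
4. one-way ANOVA with all-pairs Tukey HSD, computable either from raw
   per-egg readouts or from printed "mean +/- SD (n)" summaries;
5. a synthetic CAM generator with analytic ground truth that makes every
   stage testable without any microscope.

## The segmentation model

The segmenter is a compact U-net style network: `depth = 4` resolution
levels with one 3x3 convolution + ReLU per level (base width 16, doubling
per level), 2x2 max pooling on the way down, nearest-neighbour upsampling
with skip-connection concatenation on the way up, and a 1x1 sigmoid head.
Training minimises per-pixel binary cross-entropy with Adam
(`lr = 1e-3`), with augmentation (flips, right-angle rotations, integer
translations, additive color shifts), and early stopping on the pooled
validation Dice score (patience 4, at most 10 epochs). Every random draw
-- weight initialisation, augmentation, batch order -- flows from one
config seed, so a training run is a pure function of (data, config).

The network is implemented from first principles in RcppArmadillo
(im2col + SGEMM convolutions with hand-written backpropagation) because
the deployment environment provides no neural-network framework; the
backward pass is unit-tested against finite differences. The small
architecture is a deliberate choice: on the synthetic curriculum it
exceeds the published quality bars (Dice 0.83, precision 0.79, recall
0.88) within one epoch on a single CPU, and a bigger model would only
slow the reproducible desk-scale runs. Inference on images larger than
`tile_size` (256 px) proceeds in overlapping tiles (overlap 32 px)
blended with linear feathering; smaller images are padded reflectively to
a multiple of 8 and cropped back.

Score maps are binarized with an inclusive threshold (score >= 0.5 is
vessel); inclusivity is a declared convention, fixed by the package's
`{0.49, 0.50, 0.51} -> {bg, vessel, vessel}` contract.

## Morphometry conventions

The assay readouts are defined on a binary mask. The paper-side platform
never documents its algorithms, so the conventions here are declared and
tested rather than inferred:

* **Area** -- vessel pixel count after removing 8-connected components
  smaller than 10 px (speckle suppression).
* **Skeleton** -- Zhang--Suen thinning followed by sequential
  simple-point erosion (a non-endpoint pixel whose ON neighbours form a
  single 8-connected component in its 3x3 ring is redundant). The second
  pass removes the staircase doublings that parallel thinning is known to
  leave; without it, junction and length estimates are badly biased.
* **Length** -- the skeleton is traced into branch polylines between
  endpoints and junctions, each branch is simplified with Douglas--Peucker
  (tolerance 0.8 px) and measured as the Euclidean length of the
  simplified polyline. On straight runs this reproduces the classical
  step values exactly (a horizontal run of n pixels measures n-1; a 45
  degree run (n-1)*sqrt(2)); on oblique runs it avoids the +5--8%
  digitization bias of raw chain-code sums, which would otherwise exceed
  the +/-5% ground-truth tolerance no matter how exact the skeleton. The
  chain-code convention remains available as `method = "chain"`.
* **Branching points** -- skeleton pixels with crossing number >= 3
  (three or more departing branches), clustered so that the junction
  cluster of one thick vessel counts once: candidates merge within a
  Chebyshev distance of 2, or within the local vessel radius (from the
  distance transform) when the mask is available. The thickness-adaptive
  radius matters for vessels tens of pixels wide, whose Y-junctions thin
  into two 3-way pixels several pixels apart.
* **Thickness** -- mean over skeleton pixels of `2*EDT - 1`, where EDT is
  the exact Euclidean distance to the nearest background pixel
  (Felzenszwalb--Huttenlocher transform). On the integer raster this
  measures the discrete width: a capsule of radius 5 drawn at integer
  phase is 11 px wide and measures 11. The estimator carries a <= 1 px
  negative bias on even discrete widths; this is inherent to the
  convention, not a bug, and bounds how thin a vessel can be before a
  10% agreement with continuous ground truth becomes unattainable.
* `quantify()` composes all four readouts after one shared
  component-filtering pass and prunes terminal skeleton spurs shorter
  than 12 px (outline-bulge artifacts of thinning) before the
  skeleton-based readouts.

## The synthetic world

The generator grows parametric vessel trees by a jittered random walk
with stochastic tip bifurcation: at each step a tip turns by
N(0, `curvature_sd`) radians and, with probability `branch_probability`,
ends in a bifurcation whose two children take `taper_factor` times the
parent radius (children never exceed the parent, and children that would
fall below the minimum diameter are clamped to it and stop branching, so
deep trees contain vessels at the lower diameter bound). Radii are
constant within a segment; branching points, arc lengths, areas and the
length-weighted mean diameter are therefore available analytically and
serve as ground truth for the morphometry oracle.

Rendering composes, on a pink-yellow membrane with a low-frequency
illumination field: an optional pale tumor disc (drawn *under* the
vessels -- vessels grow over the graft, and occluding them would poison
the training labels), blurred pale "deep" vessels (sigma 4 px) that
emulate sub-membrane vasculature, sharp dark-red superficial vessels
(sigma 0.8 px), and Gaussian sensor noise (SD 0.025 on the unit scale).
Whole root subtrees are flagged deep with probability
`deep_fraction = 0.15`; deep vessels are rendered but excluded from the
ground-truth mask, exactly the label the real application was trained to
produce. Perfusion sequences, by contrast, include deep segments --
speckle imaging sees sub-membrane flow -- with one PU level per segment
drawn from `pu_vessel_range = c(1200, 2600)` (inside the 800--3000 PU
analysis band) over a background of 120 PU, per-pixel frame noise of
SD 20 PU, and an optional global +600 PU offset on designated motion
frames. The default calibration, 0.1 mm/px on a 100 x 110 px field,
reproduces the 1 cm x 1.1 cm measurement frame of the assay protocol.

What the generator does *not* emulate: real membrane texture, specular
reflections from the shell window, chromatic vignetting, embryo motion
within a frame (only global offsets between frames), and annotation
noise -- real training masks are hand-drawn and imperfect, synthetic ones
are exact. A green acceptance suite therefore establishes that the
pipeline is implemented correctly, not that the published accuracy
transfers to real eggs.

## Oracle suites and their stated tolerances

The ground-truth-consistency criterion (quantify vs analytic tree:
area exact/3%, length +/-5%, thickness +/-10%, branch count exact) is
defined *on trees with well-separated segments*; on dense trees vessels
merge and the analytic readouts are simply not what any mask-based method
measures. The suite is built by rejection sampling with
`tree_well_separated()`: branch vertices at least 3x the maximum radius
apart, no two segments approaching closer than the sum of their radii
plus a clearance (4 px), every child emerging from its parent's capsule,
plus minimum-size requirements (>= 4 segments, >= 500 px of vasculature).
The suite's diameter floor of 16 px follows from the thickness
estimator's <= 1 px discretization bias: below ~10 px diameter the
convention itself uses up the whole +/-10% budget. Within this world the
acceptance suite holds with margins (50/50 trees: length within +/-4%,
thickness within -9.1%, branch count exact everywhere).

The detection-range suite pins the diameter extremes structurally: its
first tree carries a 220 px root and its second a 3 px root on a 512 px
canvas, so "both extremes detected" is a statement about the segmenter,
never about sampling luck.

## Numerical and degenerate-input choices

* Thresholds: binarization inclusive at 0.5; PU band inclusive at both
  800 and 3000.
* Empty-denominator metrics: both masks empty -> Dice/precision/recall
  all 1; exactly one empty -> all 0.
* Empty skeleton: `mean_thickness()` errors; `quantify()` reports 0 with
  an `empty_skeleton` flag so batch tables stay rectangular.
* Stable-window selection: the k-frame window minimising the maximum
  frame-to-frame mean |dPU|, earliest window on ties; `k = 1`
  degenerates to the first frame. No window under the tolerance is an
  explicit error, mirroring an operator who would keep recording.
* Zero within-group variance in ANOVA is handled as the limit (F and the
  studentized range go to infinity; p to 0) rather than by an epsilon.
* Tukey HSD uses Tukey--Kramer standard errors with the pooled error
  degrees of freedom, the classical homoscedastic reading of the
  "appropriate one-way ANOVA" followed by common statistics packages.
  The summary-statistics path rebuilds SS-between from means and
  SS-within from (n-1)sd^2 and shares the core with the raw path, so
  their equivalence is exact by construction; the raw path itself is
  validated against `aov()`/`TukeyHSD()` in the tests.
* EDT at image borders uses in-image background only, slightly inflating
  the thickness of border-hugging vessels; the synthetic generators keep
  vessels inside the canvas.

## Known limitations

* The published biological group means (vessel length, branching points,
  perfusion) derive from images that were never deposited; they cannot be
  recomputed, only their statistical analysis can (and is, from the
  printed summaries).
* The segmenter is trained and validated on synthetic imagery; no claim
  is made about transfer to real CAM photographs without retraining.
* Thickness below ~10 px diameter is systematically underestimated by up
  to 1 px by the declared discrete convention.
* The perfusion module consumes instrument-style PU maps; raw speckle
  processing (K = sd/mean, flow ~ 1/K^2) ships only as an optional
  utility (`speckle_contrast()`) and is not part of the analysis chain.
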