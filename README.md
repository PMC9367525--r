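# vascam

Quantification of tumor-induced angiogenesis in the in ovo chick
chorioallantoic membrane (CAM) assay: a trainable encoder–decoder vessel
segmenter, skeleton-based vascular morphometry, an LSCI-style perfusion
summary, and the assay's group statistics — plus a synthetic CAM
generator with analytic ground truth so the whole pipeline is testable
without a microscope.

## Who this is for

Labs that image tumor grafts on the CAM and want an open, reproducible
counterpart to closed web-platform analyses: per-pixel vessel
segmentation of RGB microscopy images, the four standard readouts from
the binary mask, perfusion summaries from laser speckle contrast imaging
(LSCI) frame stacks, and the one-way ANOVA + Tukey HSD comparisons used
to report such experiments — including the case where only printed
"mean ± SD (n)" values survive.

## The model and statistics in brief

**Segmentation.** A compact U-net style network (4 levels, one 3×3
convolution + ReLU per level, base width 16, max-pool down,
nearest-neighbour up with skip concatenation, 1×1 sigmoid head) maps an
RGB image to a per-pixel vessel score in [0, 1]; the mask is
`score ≥ 0.5`. Training: per-pixel binary cross-entropy, Adam, flip /
rotation / shift / color augmentation, early stopping on validation
Dice. Evaluation: pooled pixel-wise Dice `2TP/(2TP+FP+FN)`, precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`.

**Morphometry** on the binary mask `M`: total vessel area `|M|` (px²,
after small-component removal); skeleton by thinning + simple-point
cleanup; total vessel length as the geodesic length of the simplified
centerline polylines (px); branching points as clustered skeleton
junctions (crossing number ≥ 3); mean vessel thickness as the mean of
`2·EDT − 1` over skeleton pixels (px), EDT the Euclidean distance
transform.

**Perfusion.** From a stack of PU maps: select the most stable run of
`k = 10` consecutive frames (minimax frame-to-frame mean |ΔPU|), average
them, keep pixels with `800 ≤ PU ≤ 3000`, and report mean perfusion
(PU), perfused area (mm²) and mean blood flow = mean PU × area (PU·mm²).

**Statistics.** Fixed-effects one-way ANOVA, then all-pairs Tukey HSD via
the studentized range with pooled error df (Tukey–Kramer for unequal n),
from raw vectors or from per-group (mean, sd, n).

## Worked example

```r
library(vascam)

# a vessel tree with analytic ground truth, rendered as a CAM-like image
tree <- generate_vessel_tree(
  c(512, 512), n_roots = 2, branch_probability = 0.2,
  branch_angle_spread = pi / 2, diameter_range = c(16, 36),
  taper_factor = 0.85, deep_fraction = 0, step_px = 8, max_steps = 45,
  max_segments = 9, min_branch_gap = 6, max_depth = 3,
  curvature_sd = 0.07, seed = 33)
tree
#> <vascam_tree> 8 segments (0 deep distractors), 3 branch points, 512x512 canvas

ras <- rasterize_tree(tree)
ras$morphometrics              # analytic ground truth
#> <vascam_morphometrics> area 26413 px^2 | length 1440.0 px | thickness 18.38 px | 3 branch points

quantify(ras$mask)             # recovered from the mask alone
#> <vascam_morphometrics> area 26413 px^2 | length 1414.6 px | thickness 17.21 px | 3 branch points

smp <- render_cam_image(tree, seed = 33)   # image + truth mask + provenance
smp
#> <vascam_sample> 512x512 image, 26413 vessel px, seed 33

# perfusion summary on a uniform 1000 PU field of 10 mm x 11 mm
m <- perfusion_map(matrix(1000, 100, 110), pixel_pitch_mm = 0.1)
summarize_perfusion(m)
#> <vascam_perfusion> mean 1000.0 PU | area 110.00 mm^2 | flow 110000.0 PU.mm^2

# group comparison from printed summaries (total vessel area, 1e4 px^2)
cells <- summary_stats(c("ctrl_d11", "ctrl_d16", "glc_d11", "glc_d16"),
                       mean = c(10.31, 12.56, 9.66, 10.27),
                       sd   = c(2.76, 2.95, 2.93, 2.62),
                       n    = c(25, 25, 25, 25))
anova_tukey_from_summary(cells)
#> One-way ANOVA: F(3, 96) = 5.118, p = 0.002504
#> Tukey multiple comparisons:
#>   ctrl_d11 vs ctrl_d16: diff = -2.25, p.adj = 0.02908 *
#>   ctrl_d11 vs glc_d11: diff = 0.65, p.adj = 0.847
#>   ctrl_d11 vs glc_d16: diff = 0.04, p.adj = 1
#>   ctrl_d16 vs glc_d11: diff = 2.9, p.adj = 0.00247 **
#>   ctrl_d16 vs glc_d16: diff = 2.29, p.adj = 0.02537 *
#>   glc_d11 vs glc_d16: diff = -0.61, p.adj = 0.8699
```

Area is recovered exactly, length within 2%, thickness within 7% and the
branch count exactly — the mask-vs-truth agreement guarantees hold on
well-separated trees like this one (see the methods vignette and
`tree_well_separated()`); on dense, overlapping vasculature the analytic
polylines and any mask-based measurement legitimately diverge.

The control day-11 vs day-16 vessel-area comparison is significant
(p = 0.029 < 0.05) while the treated group's is not — the same pattern
the assay reports.

## Command line

```sh
Rscript inst/cli/vascam.R simulate --n 5 --canvas 512 --seed 7 --out-dir sim
Rscript inst/cli/vascam.R train --data-dir sim --val-n 2 --out model.rds
Rscript inst/cli/vascam.R segment --model model.rds --input sim --out-dir seg
Rscript inst/cli/vascam.R quantify --masks seg --out morphometrics.csv
Rscript inst/cli/vascam.R perfusion --frames frames.tif --pitch 0.1 --out perfusion.csv
Rscript inst/cli/vascam.R stats --input morpho_long.csv --out comparisons.csv
```

(after installation, `inst/cli/vascam.R` resolves via
`system.file("cli", "vascam.R", package = "vascam")`).

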