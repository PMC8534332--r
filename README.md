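# sonomorph

Morphology and motion-phase analysis of median-nerve segmentation masks from
dynamic ultrasound.

## The problem

In carpal tunnel syndrome the median nerve is entrapped at the wrist, and
dynamic ultrasound — imaging while the fingers flex and extend with the probe
held still — reveals how the nerve slides and deforms over each motion cycle.
Deep-learning models can segment the nerve in every frame, but the clinically
interesting quantities live *downstream* of segmentation: the nerve's
cross-sectional area (CSA), centroid trajectory, perimeter and circularity per
frame; the flexion/extension phases of the motion; and pooled temporal
profiles of these metrics on a normalized time base. `sonomorph` implements
that post-segmentation pipeline for anyone working with binary nerve masks
(model predictions or manual annotations), plus the evaluation metric
(intersection over union) used to score predicted masks, and a synthetic
generator of moving, deforming nerve mask sequences so the whole pipeline can
be exercised and tested without access to clinical data.

## The quantities it computes

For a binary mask f(x, y) on a w x h grid (x rightward, y downward, 0-based):

* **CSA** — the zeroth moment, `CSA = sum_x sum_y f(x, y)`, i.e. the
  foreground pixel count, convertible to cm^2 through the pixels-per-cm scale.
* **Centroid** — the first moments,
  `cx = sum x f(x, y) / CSA`, `cy = sum y f(x, y) / CSA`.
* **Perimeter** — chain-code arc length of the outer border: Moore border
  following through foreground pixel centres, axis steps of 1 and diagonal
  steps of sqrt(2), closed polygon.
* **Circularity** — `4 pi CSA / p^2`; 1 for an ideal circle, ~0.605 for an
  equilateral triangle. (Digitization matters: the chain-code perimeter of a
  smooth convex shape runs up to ~5% long, so rasterized-disc circularity
  computes to ~0.9, not 1.0 — see the methods vignette.)
* **IoU** — `|A intersect B| / |A union B|` per frame, averaged per video.

Multi-region predictions are resolved per frame by the largest-area rule
(semantic output) or by taking the largest block inside the highest-confidence
candidate (instance output). Phases are segmented from the biphasic centroid
displacement pattern, phase durations are histogrammed with D90/D50 modal
ranges, and each phase's metric trace is resampled at 30 normalized-time
points u_k = k/29 and pooled into mean +/- SD profiles.

## Worked example

```r
library(sonomorph)

# simulate one subject's video: ~5 flexion/extension cycles at 38 fps,
# sampled every 4th frame, 100 px/cm
sim <- generate_truth(sim_spec(seed = 42))
sim
#> <sim_truth> 60 frames, 10 phases, total 6.25 s

# degrade into a synthetic model prediction and resolve each frame
# to a single nerve mask by the largest-area rule
deg  <- degrade(sim, noise_spec(seed = 43))
pred <- postprocess_sequence(deg$semantic, "semantic")
evaluate_video(pred, sim$sequence)
#> <iou_report> 60 frames counted (invalid frames counted)
#>   video average IoU: 0.9123

# per-frame morphology and flexion/extension phases
met <- sequence_metrics(pred)
ph  <- segment_phases(met)
ph
#> <phase_set> 8 phases (4 flexion, 4 extension)
duration_histogram(ph, "flexion")
#> <duration_histogram> flexion: 4 phases, bin width 0.03 s
#>   D90: 0.630-0.660 s, D50: 0.630-0.660 s

# pooled 30-point normalized profile of the cross-sectional area in flexion
prof <- pool_profiles(ph, "csa_cm2", "flexion")
prof
#> <normalized_profile> csa_cm2, flexion phase, 4 phases pooled, 30 points
#>   mean range: 0.1019-0.1133
round(prof$mean[c(1, 15, 30)], 4)
#> [1] 0.1133 0.1060 0.1019
```

Reading the output: the synthetic prediction scores an average IoU of 0.91
against its ground truth; the detector finds the 8 interior flexion/extension
phases of the 5 programmed cycles (the leading and trailing half-phases have
no bracketing turning points); the most frequent flexion duration falls in the
0.63-0.66 s histogram bin; and the pooled flexion CSA profile falls from
0.113 cm^2 at the phase start to 0.102 cm^2 at peak flexion — recovering the
programmed ~12% area shrink (0.1019/0.1133 - 1 = -10%, the residual being
temporal-quantization truncation at the phase boundaries; see the vignette).

A command-line interface over the same functions ships at
`inst/cli/sonomorph.R` with subcommands `simulate`, `metrics`, `phases`,
`profiles` and `evaluate`.

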