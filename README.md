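# scanpathr

Gaze-pattern analysis of scene perception and visual mental imagery in R.

When people imagine a picture on a blank screen, their eyes revisit the
regions they fixated while seeing it — the *looking-at-nothing* effect. The
finer structure of those eye movements can tell us *how* the mental image is
built: if imagery scanpaths resemble part-by-part viewing (forced
experimentally by a **gaze-contingent window**, GCW, that shows only the
fixated region) more than holistic viewing (forced by an **artificial
scotoma**, AS, that masks the fixated region), imagery is plausibly a
part-based construction process. `scanpathr` provides the complete toolkit
for this kind of study, for cognitive scientists working with fixation
reports from video eye trackers:

* **Recurrence quantification analysis (RQA)** of fixation sequences. Two
  fixations are recurrent when `‖x_i − x_j‖ ≤ ε` (default ε = 2.5° of visual
  angle = 135 px at the default geometry). From the recurrence matrix the
  package computes the recurrence rate `100·2R/(n(n−1))`, **determinism**
  (`100·D/R`, the share of recurrence points on diagonal lines of ≥ 2 points
  — refixations repeating in their original order), **laminarity**
  (`100·(H+V)/(2R)`, points on horizontal/vertical lines — clustered
  dwells), and the fixation-spread covariate (RMS distance from the
  centroid).
* **Five-dimension scanpath similarity** in the MultiMatch vector-alignment
  style: shape, length, direction, position and duration similarities in
  [0, 1] after saccade-vector simplification and optimal monotone alignment.
* **Quadrant AOI profiles** and the looking-at-nothing association (least
  squares slope of imagery on encoding proportions across pair × quadrant
  points).
* **Fixation filtering** (off-screen, < 100 ms, > 5000 ms) with quality
  summaries, and a **velocity/acceleration fixation detector**
  (30°/s, 8000°/s²) for raw 1000 Hz sample tracks.
* **Participant-level cluster-bootstrap condition contrasts** (a
  sampler-free substitute for hierarchical zero-one-inflated beta models).
* A **seeded synthetic scanpath generator** emulating free viewing,
  part-based viewing, holistic viewing and imagery-like gaze, so every
  stage is testable without any recorded data.

## Worked example

```r
library(scanpathr)

# 1920x1080 screen at 855 mm, calibrated so 5 deg spans 270 px
geom <- screen_geometry()
deg_to_px(c(2.5, 5, 7), geom)
#> [1] 135 270 378

# a synthetic part-based (gaze-contingent window) encoding trial
cfg <- cohort_config(n_participants = 6, n_trials = 6, n_fixations = 25,
                     seed = 1)
enc <- generate_trial(cfg, "part_based", participant = "p01", trial = "t01",
                      seed = 101)
rqa(enc)
#> <rqa_result> n = 25, R = 32 | REC 10.67%, DET 59.38%, LAM 71.88%, spread 478.8 px

# an imagery trial replaying that encoding, compared on five dimensions
img <- generate_trial(cfg, "imagery", encoding = enc, seed = 102)
similarity_profile(img, enc)
#> <similarity_profile> 20 aligned vector pairs
#>     shape    length direction  position  duration
#>    0.9356    0.9137    0.5719    0.8507    0.6834
```

The recurrence result says that 10.7% of this trial's fixation pairs land
within 135 px of each other, that 59% of those recurrences repeat in their
original sequential order (high determinism — the signature of part-by-part
inspection), and that 72% belong to clustered dwells (high laminarity). The
similarity profile shows the imagery trial reproducing the encoding trial's
overall vector shape and amplitudes (≈ 0.93) and its spatial layout
(position 0.85) much better than the exact saccade directions or fixation
durations.

The full pipeline — simulate or read fixations, filter, per-trial RQA,
imagery-vs-encoding similarity, looking-at-nothing fit, bootstrap contrasts,
behavioural summary, manifest — runs from one config:

```r
res <- run_pipeline(demo_config(seed = 1))
res
#> <pipeline_result> /tmp/.../scanpathr-run-...
#>   72 scanpaths, 72 RQA rows
#>   LAN slope 0.687
res$contrasts[, 1:5]
#>           measure contrast point_estimate    ci_low   ci_high
#> 1 recurrence_rate  MI - FP       6.014974  5.188406  6.711713
#> 2     determinism  MI - FP      25.955623 14.945423 35.631730
#> 3      laminarity  MI - FP      48.690690 44.075829 52.799860
```

On this synthetic cohort the imagery phase (MI) recurs more, is more
deterministic and more laminar than free-perception encoding (FP), with 95%
bootstrap intervals well away from zero, and the looking-at-nothing slope
0.69 recovers the generator's encoding→imagery coupling of 0.7. A YAML
version of this configuration ships in `inst/extdata/demo-config.yaml`, and
`inst/scripts/scanpathr-cli.R` exposes the stages as shell subcommands
(`simulate`, `preprocess`, `rqa`, `similarity`, `lan`, `contrast`,
`run-all`).

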