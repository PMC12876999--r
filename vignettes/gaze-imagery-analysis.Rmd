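---
title: "Analysing gaze patterns in perception and visual mental imagery"
author: "scanpathr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing gaze patterns in perception and visual mental imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanpathr)
```

## The scientific problem

When people visually imagine a scene on a blank screen, their eyes do not
rest: fixations return to the screen regions that were fixated while the
scene was perceived — the *looking-at-nothing* (LAN) effect. Beyond this
coarse spatial reinstatement, the *dynamics* of imagery gaze carry
information about how a mental image is built. If imagery scanpaths resemble
those produced under a **gaze-contingent window** (GCW — only a small region
around fixation is visible, forcing part-by-part inspection) more than those
produced under an **artificial scotoma** (AS — the region around fixation is
masked, forcing holistic, peripheral viewing), this supports a part-based
account of mental image generation.

`scanpathr` implements the three families of measures that such a comparison
rests on, a velocity-based fixation detector, the standard fixation filters,
a bootstrap contrast procedure, and a fully seeded synthetic scanpath
generator so that every stage — and every directional claim — can be tested
without any recorded eye-tracking data.

## Data model and geometry

The analysis atom is the **fixation** (onset, duration, x, y); the analysis
unit is the **scanpath**: the ordered fixation sequence of one participant ×
trial × phase (`encoding`, `imagery`, `reinspection`), with screen geometry
attached. Coordinates are screen pixels, origin top-left, 0-based, possibly
fractional; times are in milliseconds.

Angles and pixels are linked through the exact tangent chord formula
$\mathrm{extent} = 2\,d\,\tan(\theta/2)/\mathrm{pitch}$ with the pixel pitch
fixed by a calibration pair. The default geometry — a 1920 × 1080 display at
855 mm with 5° ≙ 270 px — reproduces the calibration pair exactly and maps
2.5° to 135 px, the recurrence radius used throughout. Final pixel sizes
round half-up; we do not use a small-angle linear scale, so conversions stay
principled at 7° and beyond. (At this geometry a 7° mask diameter computes
to 378 px; reported hardware setups sometimes round such values differently
by a pixel.)

## Preprocessing

`filter_fixations()` applies the standard fixation-report filters: it
removes fixations off the screen, shorter than 100 ms, or longer than
5000 ms. Two boundary rules are pinned deliberately, since they are usually
left unstated:

* duration cut-offs are **strict** (`<` / `>`): a fixation of exactly 100 ms
  or exactly 5000 ms is kept, reading "shorter than"/"longer than"
  literally;
* the screen is the **half-open** rectangle $[0, w) \times [0, h)$: a
  position exactly at the width or height is off-screen.

Removal reasons are checked in a fixed order (off-screen → short → long) so
the per-reason counts partition the removals, and filtering is idempotent.
`qc_summary()` compares participants on total fixation time, fixation count
and mean duration through z-scores and *flags* |z| > 3 — it never excludes
anyone automatically; exclusion is an analyst's decision.

## Event detection

`detect_fixations()` is a velocity/acceleration threshold detector for raw
gaze samples: the pixel trace is converted to visual angle about the screen
centre, smoothed with a centred moving average (5 samples), and
differentiated by central differences. A sample is fixational iff the pupil
is valid and speed < 30°/s **and** |acceleration| < 8000°/s² — strict
inequalities, so a sample exactly at threshold is saccadic. Maximal
fixational runs spanning at least 40 ms become fixations (centroid position,
first-sample onset, run-length duration); invalid (blink) samples break
runs, which is why a blink inserted mid-fixation splits it in two.

Commercial parsers implement unpublished smoothing and duration heuristics;
this detector is a documented, reproducible estimator of the same events,
not a sample-for-sample replica of any vendor parser. On noise-free
synthetic tracks it recovers the generating fixation count exactly and
onsets within one smoothing window.

## Quadrant AOIs and the looking-at-nothing association

`aoi_profile()` divides the screen into four equal quadrants (half-open
cells; midline points belong to the right/lower quadrant, so the quadrants
partition the screen) and returns fixation proportions.
`lan_association()` pools the per-trial (encoding, imagery) profile pairs
into (pair × quadrant) points and fits imagery proportion on encoding
proportion by ordinary least squares. A positive slope is the LAN effect.

The original analyses of such designs use hierarchical zero-one-inflated
beta regression; that machinery needs an HMC sampler and is deliberately
*not* re-implemented. The pooled descriptive slope preserves exactly the
property under test — the sign and strength of the encoding→imagery spatial
coupling. Under the generator's per-fixation mixing model (imagery fixation
= encoding location with probability λ, fresh uniform location otherwise,
zero jitter), the population slope equals λ: conditioning on the *observed*
encoding proportions makes the expected imagery proportion
$\lambda\,\hat p + (1-\lambda)/4$, so there is no errors-in-variables
attenuation. Imagery jitter pushes fixations across quadrant borders and
shrinks the slope below λ, which is why the slope-recovery tests use the
zero-jitter mixing construction.

## Scanpath similarity (five dimensions)

`similarity_profile()` follows the vector-comparison framework: a scanpath
of $n$ fixations becomes $n-1$ saccade vectors, the two vector sequences are
simplified and aligned, and five normalized dissimilarities are averaged
over aligned pairs — similarity is one minus the mean:

| dimension | dissimilarity per aligned pair $(u, v)$ |
|---|---|
| shape | $\lVert u - v\rVert / (2\,\mathrm{diag})$ |
| length | $\bigl|\,\lVert u\rVert - \lVert v\rVert\,\bigr| / \mathrm{diag}$ |
| direction | angular difference $/\ \pi$ |
| position | distance between saccade endpoints $/\ \mathrm{diag}$ |
| duration | $|d_u - d_v| / \max(d_u, d_v)$ |

All five scores live in $[0,1]$; identical scanpaths score 1 everywhere, and
shape/length/direction/duration are translation invariant while position is
not. Two equal-amplitude orthogonal saccades give direction similarity
$1 - (\pi/2)/\pi = 0.5$.

**Simplification** iteratively merges consecutive saccade pairs that are
either both shorter than 10% of the screen diagonal or within 45° in
direction, in both cases only when the intervening fixation is briefer than
300 ms; merging sums the vectors and pools the originating-fixation
durations, and passes repeat to a fixed point. The thresholds are the common
defaults of this algorithm family and are all exposed as arguments. **Alignment** minimizes the summed magnitude of vector
differences over monotone lattice paths (steps right/down/diagonal) by
dynamic programming; ties prefer the diagonal step. On small instances the
path cost is verified against exhaustive enumeration of all monotone paths.
Per-pair dissimilarities are pooled with the mean by default (`aggregate =`
accepts the median); the duration dissimilarity is normalized per pair by
the larger duration, which keeps it in $[0,1]$ without a global constant.
Zero-amplitude vectors have no direction and are treated as directionally
matching.

## Recurrence quantification

Two fixations are **recurrent** when their Euclidean distance is at most the
radius ε (inclusive: a pair at exactly ε recurs), giving the symmetric
boolean recurrence matrix with an all-true main diagonal. The default radius
is 2.5° of visual angle — 135 px at the default geometry — a scale covering
the fovea into the parafovea. With $R$ the number of recurrent pairs in the
upper triangle and $n$ fixations:

* **recurrence rate** $= 100 \cdot 2R / (n(n-1))$ — the standard
  fixation-RQA normalization;
* **determinism (DET)** $= 100 \cdot D / R$, where $D$ counts upper-triangle
  recurrence points on diagonal lines of at least $L_{\min} = 2$ points —
  refixation runs repeating in the original order;
* **laminarity (LAM)** $= 100 \cdot (H + V) / (2R)$, where $H$ and $V$ count
  points on horizontal and vertical runs of at least $L_{\min}$ points
  scanned in the upper triangle — dwells where a region is inspected or
  reinspected with consecutive fixations. The $2R$ denominator is the
  full-matrix recurrence count, which the two upper-triangle run families
  represent by symmetry; summing $H + V$ keeps the literal "horizontal and
  vertical lines" reading while staying bounded by 100.

When no pair recurs ($R = 0$), DET and LAM are defined as 0 and the result
is flagged degenerate.

**Line counting at the matrix border.** Plain maximal-run counting
undercounts structure truncated by the matrix border: in a fully recurrent
plot (all fixations within ε) the corner point $(1, n)$ sits on a diagonal
of length one and plain counting yields DET < 100 for a perfectly
deterministic sequence. We therefore use border-completed counting: a
maximal run also qualifies when it fills its entire diagonal, row or column
segment. This is the established border-effect correction for recurrence
line counting; it makes a fully recurrent plot score exactly 100 on all
three measures, leaves isolated interior recurrences at 0, and does not
change the ordered-cluster-tour case (A,B,C,A,B,C → DET 100, LAM 0). Its
price is that the few border cells (the corner diagonal; the single-cell
first-column/last-row segments) always qualify when recurrent; with very
sparse recurrence this adds at most a couple of points to the counts, which
matters only when $R$ is tiny — see Limitations. Both the implementation and
the independent brute-force oracle used in the tests implement this pinned
convention, so oracle equivalence is exact, not approximate.

**Fixation spread**, the covariate reported alongside the recurrence
measures (dispersed scanpaths mechanically recur less), is not given a
formula in the literature we follow; we define it as the root-mean-square
distance of the fixations from their centroid, which is 0 for a point and
half the separation for a symmetric pair.

## The synthetic generator

The generator is anchor-based rather than image-salience-based: the
constructs being tested (spatial indices, part revisits, dwells, sequential
order) map directly onto a set of anchor locations, and no stimulus images
are needed. Each trial places `n_anchors` anchors uniformly with a minimum
pairwise separation of 300 px (comfortably above twice the recurrence
radius, so distinct anchors never recur through jitter); if the anchors
cannot be packed a configuration error is raised. A scanpath is a sequence
of anchor visits; each visit emits `1 + Poisson(cluster_dwell − 1)`
fixations with Gaussian within-anchor jitter. After the initial tour, each
visit either revisits (probability `revisit_prob`) — following the original
first-visit order with probability `order_fidelity`, else a random visited
anchor — or explores a fresh location reached by a gamma-distributed jump
(shape 4, mean `saccade_scale`), a genuinely large-amplitude saccade with
negligible mass inside one recurrence radius. Durations are log-normal
(median 250 ms, σ ≈ 0.35 on the log scale) clamped into [100, 5000] ms, the
plausible fixation range that also survives the preprocessing filters.

The four regimes are lever presets (`mode_preset()`):

| regime | revisit | order fidelity | dwell | jitter |
|---|---|---|---|---|
| free | 0.30 | 0.20 | 1.0 | 15 px |
| part_based (GCW) | 0.60 | 0.90 | 2.5 | 10 px |
| holistic (AS) | 0.05 | 0.00 | 1.0 | 5 px |
| imagery | 0.70 | 0.85 | 2.0 | 25 px |

Free viewing mixes exploration with occasional unordered revisits; the
gaze-contingent window forces systematic, ordered, clustered re-inspection;
the artificial scotoma forces dispersed large jumps with almost no revisits;
imagery *replays*: it cycles (with fidelity `order_fidelity`) through a
subset of the encoding fixation locations of the same trial, emitting dwells
with jitter, and each fixation uses the encoding location with probability
λ = `encoding_coupling` (default 0.7) or a fresh uniform location otherwise.
With λ = 1, zero jitter, unit dwell, full fidelity and as many anchors as
fixations, imagery reproduces the encoding scanpath exactly — the limiting
case used by the slope-recovery tests.

A master seed is streamed into per-(participant, trial, phase) substreams,
so cohorts are bit-reproducible and extensible without reshuffling earlier
trials. `render_raw_track()` turns any scanpath into a 1000 Hz sample track
(piecewise-stationary positions plus optional Gaussian noise, saccadic
transitions paced at ~300°/s, optional blink gaps) for testing the detector.

What the generator *does* emulate: refixation rate, refixation clustering,
sequential-order fidelity, saccade-amplitude regime, encoding→imagery
spatial coupling, plausible duration marginals. What it does *not*: image
content and salience, centre-of-screen bias, duration–amplitude
correlations, smooth pursuit, drift, or the magnitudes of any human
condition effects. Passing the directional tests therefore shows that the
pipeline *orders the regimes correctly when the generating mechanisms are
known*; it does not calibrate effect sizes to human data.

## Condition contrasts

`condition_contrast()` replaces the hierarchical Bayesian zero-one-inflated
beta models of the original analysis chain with a descriptive,
dependency-free procedure: the point estimate is the mean over participants
of the within-participant difference of condition means (independent means
when the design is unpaired), and uncertainty comes from a percentile
bootstrap that resamples *participants* — the exchangeable clusters — never
trials within participants. The decision rule (sign of the estimate, whether
the 95% interval excludes zero) is preserved; posterior distributions,
priors and inflation components are out of scope. Under a simulated null
(50 participants, no true difference) the 95% intervals exclude zero in
about 5% of replicates, which the test suite checks at ±2 points. Intervals
are bit-reproducible given (seed, `n_boot`).

## The pipeline

`run_pipeline()` chains the stages — synthesize or read a fixation report,
filter, per-trial RQA, imagery-vs-encoding similarity profiles, the LAN
fit, bootstrap contrasts, behavioural summary — and archives every table as
TSV plus a JSON manifest (package version, seed, content hash of the
configuration). Two reproducibility rules are worth stating: the pipeline
analyses the *archived* fixation report it writes (the canonical dialect
stores positions at two decimals), so re-running the analysis from the
written file reproduces the run bit-for-bit; and re-running into a used
output directory requires `overwrite = TRUE`. A thin command-line
dispatcher over these functions ships in `inst/scripts/scanpathr-cli.R`.

## Numerical choices and degenerate inputs

* Pixel sizes round half away from zero (base `round()` is banker's).
* Alignment ties prefer the diagonal step; symmetric instances with exact
  cost ties may align differently under operand swap, though all minimal
  paths have equal cost.
* DET/LAM with $R = 0$ return 0, flagged; empty AOI profiles are flagged
  undefined and dropped from the LAN fit; a LAN fit needs ≥ 2 pairs and a
  predictor with non-zero variance.
* A scanpath needs ≥ 2 fixations for saccade vectors, recurrence and spread;
  detection needs ≥ 3 samples and ≤ 10% sampling jitter.
* Scanpath onsets must be strictly increasing; violations are data errors
  naming the offending group.

## Problem sizes used by the test suite

The directional and calibration checks run at sizes chosen to keep the whole
suite fast while leaving comfortable statistical margins: 200 trials per
regime arm across 20 reseeded repetitions for the regime ordering; 200
trials for slope recovery; three settings × 120–200 trials per generator
lever; 500 random scanpaths (n between 5 and 40) for exact oracle
equivalence; 400–500 replicates × 1000 bootstrap resamples for null
calibration. The order-fidelity lever is probed with the revisit rate held
at 0.7: order fidelity only governs revisits, so at low revisit rates the
lever has almost nothing to act on and its effect would drown in noise.

## Known limitations

* The LAN slope is a pooled descriptive statistic; it ignores participant
  hierarchy and the boundedness of proportions. It is the right tool for
  sign-and-coupling questions, not for reproducing model-scale estimates.
* With very sparse recurrence (e.g. the holistic regime, a few recurrent
  pairs per trial), DET and LAM are ratios of tiny counts: single
  border-completed points can move them by tens of percentage points, so
  regime means for near-degenerate scanpaths should be read qualitatively.
* The detector's exactness claims hold for noise-free tracks; realistic
  noise (≈ 0.05° at 1000 Hz) occasionally splits long fixations, as it does
  for real trackers.
* Similarity scores depend on the simplification thresholds; comparisons
  are meaningful only within one parameter setting.
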