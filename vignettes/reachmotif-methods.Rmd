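---
title: "Models and methods behind reachmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reachmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachmotif)
```

`reachmotif` analyzes skilled forelimb water-reaching in freely moving
mice. This vignette explains the models the package implements, the
assumptions they rest on, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The behavioral model

A reaching trial opens with water delivery and a 7 s response window;
inter-trial intervals are uniform on 2–15 s. Within a trial the forelimb
sequence decomposes into six stereotyped motor motifs — Lift, Reach, Open,
Grasp, Retract, Drink — plus a background NoReach state. Labels are
integer codes 0–6 with NoReach = 0. A *bout* is a maximal constant-label
run; bout order within a trial follows a bout-level (semi-Markov) chain
whose mass lies on the forward superdiagonal.

The seven-state set deserves a note: published motif listings are
inconsistent about a seventh named class, but every figure-level analysis
uses six motifs plus the background state, so the 7-class set
{NoReach + 6 motifs} is what the classifier and all metrics use.

## 3D kinematics

Two synchronized, perpendicular cameras record at 500 Hz. The package
does not perform checkerboard calibration (out of scope); instead it
assumes an ideal orthogonal camera model: the side view images the
(x, z) plane and the front view the (y, z) plane. Fusion takes x and y
from the respective views and the shared z as the confidence-weighted
mean of the two views, with per-frame confidence the minimum of the two.
This model is exactly invertible, which the test suite exploits: with
zero pixel noise, fusing and re-projecting reproduces the inputs
bit-for-bit.

Derived series: the forelimb centroid is the mean of digits 2–4 and the
paw; speed is the norm of the central-difference derivative times the
frame rate; acceleration is the same operation applied to the velocity
components; inter-digit distance is the mean pairwise distance among
digits 2–4. Differentiation uses central differences with edge
replication; an optional Savitzky–Golay filter (window 11 frames, order 3,
via `signal::sgolayfilt`) can be applied before differentiation but is off
by default, since the synthetic templates are already smooth and real
tracker noise is better handled by the confidence-based imputation.
Low-confidence keypoints (below 0.6) are marked missing and linearly
interpolated across gaps of at most 10 frames; longer gaps stay missing
and downstream operations skip those frames.

Units: synthetic data are in mm (1 px = 1 mm in the ideal camera); real
pixel data stay in px unless a mm-per-px scale is supplied. "Pairwise
inter-bodypart coordinates" is read as pairwise *distances* (15 features
for 6 bodyparts); coordinate differences would triple the feature count
without adding rotation-invariant information.

## The motif classifier

A unidirectional single-hidden-layer GRU (256 units) maps the augmented
per-frame feature set — 18 bodypart coordinates, 15 pairwise distances,
6 bodypart speeds, centroid acceleration magnitude, all z-normalized with
training statistics — to 7-class softmax probabilities, trained with
class-weighted cross-entropy. Choices the architecture description leaves
open, and what this package does:

- **Optimizer and schedule**: Adam, learning rate 2e-3, batches of 8
  chunks, at most 20 epochs with early stopping on held-out loss
  (patience 5); the best-validation weights are kept. The recurrent
  core is implemented in RcppArmadillo (batched truncated BPTT); an
  analytic-vs-numerical gradient check is part of the test suite.
- **Chunking**: non-overlapping 1000-frame chunks with hidden-state reset
  at chunk and trial boundaries — trials are independent.
- **Class imbalance**: square-root inverse-frequency class weights.
  NoReach dominates the frame count, but full inverse-frequency weighting
  over-corrects — it makes the network overcall rare motifs far from any
  true boundary (we measured a large NoReach→Lift false-positive block in
  the confusion matrix); the square-root compromise removes most of that
  while still keeping rare-class recall high. Classes absent from
  training data get zero weight with a warning.
- **Held-out split**: by whole trials (20 %), never by frames, to avoid
  temporal leakage.
- **Determinism**: initialization and batch order are drawn from the
  config seed; retraining with the same seed is bit-identical.
- **Post-processing**: predicted bouts shorter than `min_bout_ms`
  (default 20 ms) are absorbed into the longer neighbouring bout,
  repeatedly, shortest first; the operation is idempotent. Whether any
  post-hoc smoothing was used upstream is unstated, so the default is
  conservative.
- **Evaluation**: frame accuracy, per-class precision/recall/F1, a 7×7
  confusion matrix, and a boundary-tolerant accuracy that accepts a
  frame when its predicted label occurs in the reference within ±k frames
  (default k = 5, i.e. ±10 ms at 500 Hz) — motif boundaries in manual
  annotation are themselves uncertain at that scale.

## Behavior metrics

All metric definitions follow the conventions: per-motif occurrence
values are averaged within a trial, trial values are averaged per
session. A *Lift–Reach sequence* is a Lift bout whose next non-NoReach
bout is a Reach with at most 40 ms of intervening NoReach (the unit is
treated as atomic upstream without a stated tolerance; 40 ms = 20 frames
absorbs segmentation flicker without joining separate attempts). Success
requires a Drink bout *strictly* longer than 600 ms starting at or after
the first Lift–Reach sequence; success probability is conditional on
reaching, and is undefined (flagged, not 0) in sessions with no reaching
trial. Bouts straddling the response-window edge are clipped to the
window. Transition matrices are bout-level (frame-level counting would
put nearly all mass on the diagonal) and never count across trial
boundaries; rows without outgoing transitions are left all-zero and
flagged rather than renormalized.

## Photometry

The isosbestic 410 nm channel is fitted to the 470 nm channel by affine
least squares (slope + intercept — the upstream description says only
"fitted", and an affine map is the minimal model that absorbs both gain
and offset), giving ΔF/F = (F₄₇₀ − F_fit)/F_fit. A non-positive fitted
baseline is an error, not a silent division. ΔF/F is z-scored over the
whole session; trial-baseline z-scoring is reserved for the single-cell
module where the baseline window is explicitly specified. Peri-event
alignment linearly interpolates the z trace onto a uniform 50 Hz grid;
reaction-time stratification takes the fastest and slowest
⌈0.3 · n⌉ reaching trials and reports group-mean traces and their peak
latencies in a configurable search window (default 0–3 s).
Motif-kinematics correlations use Spearman rank correlation over bout
occurrences (per-occurrence rather than per-trial pairing; cells with
fewer than 5 pairs are flagged, not tested).

## Single-cell analysis

Per neuron and motif, the per-trial baseline mean z (window −2.0 to
−0.4 s before water delivery) is paired with the per-trial mean z over
that trial's motif occurrences; ΔZ is the mean paired difference and
significance comes from a two-sided Wilcoxon signed-rank test at
α = 0.05 with no multiple-testing correction by default (matching
per-cell reporting conventions; a `p_adjust` flag is provided).

Decoding is ordinary least squares with intercept from the neural
population to each of x, y, z and velocity, cross-validated over k = 5
*contiguous* time blocks — random-frame CV would leak through temporal
autocorrelation. The kinematic series is averaged within each neural
frame interval (anti-aliasing) rather than nearest-sampled. R² is
computed on the concatenated held-out predictions; weights come from a
full-data refit and are normalized per target by the largest absolute
weight. Rank-deficient designs fall back to a tiny ridge penalty
(λ = 1e-6) with a warning. The CV scheme and regularization are not
specified upstream; block CV + OLS is the documented default.

## Perturbation analysis

Control trials receive pseudo-laser windows whose water-relative offsets
are resampled from the session's stim trials — an exact permutation when
counts match, otherwise sampling with replacement — so stim and control
trials are exchangeable under a null perturbation. Metrics are computed
on bouts clipped to Within-Laser, After-Laser or Whole-trial windows
(trial end is water + response window; the upstream bound is unstated).
All paired tests operate on session means (Wilcoxon signed-rank;
Friedman across >2 levels; Spearman for trends); trial-level
distributions are exported but never tested as independent samples.
Laser-aligned analyses include only trials where a movement motif
(Lift through Retract) is ongoing at pulse onset; onset frames labeled
NoReach or Drink are excluded with counts reported. Segment statistics
take per-trial mean and extrema, then session means. The dose–response
trend statistic ranks per-level session means within each session before
the Spearman correlation with level, so between-session baseline
differences cancel. The rebound analysis searches a 1.0 s post-offset
window (no number is stated upstream beyond "immediately following")
for a Lift–Reach sequence and compares rebound-reach velocity to control
reaches across session means.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested: 500 Hz cameras, 7 s response windows, ITI uniform on 2–15 s,
reach probability 0.9 per trial, a bout-level chain with forward
probability 0.95 and abort probability 0.05 per movement motif, and
truncated-Gaussian bout durations (Lift 80, Reach 120, Open 90,
Grasp 110, Retract 150, Drink 800 ms; Drink's mean is set so successful
trials exceed the 600 ms threshold). Motif templates are half-sine
velocity profiles along motif-specific directions (Reach toward the
spout, Retract toward the mouth) with peak speeds of 150/350/80/100/300/40
mm/s; digits spread apart during Open and close during Grasp so
inter-digit features carry motif information. A log-normal per-trial
vigor factor (σ = 0.2) scales template speeds, giving the trial-to-trial
velocity variability that activity–kinematics correlation and decoding
analyses rely on. Reaction times are Gamma-distributed
(shape 4, scale 0.175 s, floor 0.1 s).

Photometry artifacts: exponential bleaching (τ = 600 s), a shared
slow motion component on both channels, and a calcium drive c(t) equal to
forelimb speed convolved with a single-exponential kernel (τ = 0.5 s,
a fast indicator qualitatively). The population model passes
W · (x, y, z, v) through the same kernel, adds Gaussian noise, and
z-scores per neuron.

Perturbations: `excite_scale` multiplies within-window frame
displacements by `velocity_scale`, with the accumulated spatial
protrusion decaying back over ~150 ms after offset; `inhibit_abort`
collapses the movement into NoReach after a configurable lag and
re-initiates a reach (velocity scaled by `rebound_gain`) shortly after
laser offset. Brief pulses are scheduled at a fixed water-relative
latency (1.0 ± 0.25 s) rather than conditioned on the trial's own bout
times — like the experimental protocol, and necessary for stim/control
exchangeability under a null perturbation; which motif a pulse hits is
decided post hoc, exactly as in the analysis.

What the generator does **not** emulate: lens distortion and calibration
error, tracker identity swaps and occlusions, biomechanical limb
constraints, spiking-level neural dynamics, hemodynamic or movement
artifacts beyond the shared-motion model, non-stationary motivation, and
the real effect sizes of motif-specific perturbation sensitivity. Tests
passing on synthetic data therefore certify the *analysis machinery*
(definitions, estimators, calibration), not performance on real videos.

## Numerical choices and degenerate inputs

Tolerances: probability rows are checked to 1e-9; the ridge fallback uses
λ = 1e-6; confidence values are clamped to [0, 1] with a warning (the
single documented silent coercion). Degenerate inputs error with named
fields: constant isosbestic channel, zero-variance traces, non-monotone
water times, inverted or incomplete laser windows, all-missing bodyparts,
unknown state labels. Ties in modulation sorting break by neuron id;
undefined values sort last. The session container is a versioned R
serialization (no HDF5 library is required); round-trips are
bit-identical and schema mismatches or corrupt files raise explicit
errors.

## Problem sizes in the shipped tests

The test suite trains the 256-unit GRU on 80 synthetic trials (held-out
split by trials), recovers a 200-trial transition matrix to sup-norm
0.05, calibrates the modulation test on 1000 null neurons, and runs 100
seeded null repetitions of the perturbation comparison — sizes chosen so
the whole suite completes in minutes on a single CPU while keeping every
statistical check adequately powered.

## Known limitations

The GRU is unidirectional, so predicted motif onsets lag truth by a few
frames (absorbed by the ±5-frame boundary-tolerant metric). The camera
model ignores distortion, so real recordings need upstream calibration.
OLS decoding reports linear information only. The generator's abort model
freezes the limb rather than producing naturalistic failed reaches.
Chemogenetic sessions are handled only as a condition flag — no
pharmacokinetics.
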