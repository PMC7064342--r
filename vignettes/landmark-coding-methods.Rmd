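---
title: "Models and conventions behind landmarkCoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind landmarkCoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmarkCoding)
```

# The task and the data model

The package analyzes sessions from a head-fixed virtual-reality task on a
linear corridor. A 40 cm wide visual cue — the landmark — stands at a fixed
track position; each trial begins at a uniformly randomized distance of
50–150 cm before it. An unmarked 20 cm reward zone starts 80 cm (short
trials) or 140 cm (long trials) past the landmark's end, so the landmark,
not the trial start, predicts where reward can be triggered by licking.
Passing the zone without licking yields a default reward; each trial ends at
reward delivery, followed by at least 3 s of dark screens (the black box).

A session is a `LandmarkSession`, an S4 extension of
`SummarizedExperiment`: rows are ROIs, columns are imaging frames (15.5 or
31 Hz), assays hold ΔF/F and optionally raw and neuropil fluorescence, the
`colData` carries time, track position, treadmill speed and lick/reward
flags, and a trial table carries the per-trial geometry. Validity methods
enforce the task invariants (strictly increasing time; position defined
exactly off the black box; per-trial monotone position up to a configurable
sensor tolerance, default 0.5 cm; the 40/20/80/140 cm geometry; every
non-black-box frame belonging to exactly one trial). The on-disk container
is a directory of CSV tables plus `meta.json`; numerics are serialized with
`%.17g`, which makes write→read the identity on doubles and the byte layout
a pure function of the session.

# Anchor alignment

Every spatial analysis re-expresses position as distance from one of three
per-trial anchors: trial onset (`start_cm`), the landmark, or the reward.
Two conventions deserve comment.

**Which edge of the landmark is "the landmark"?** The cue is 40 cm wide. We
anchor at its onset — the first visual contact — and expose
`landmarkRef = c("onset", "center", "offset")`; since reward-zone distances
are defined from the cue's end, the three conventions differ by known
constants (0, 20, 40 cm) and change no comparison.

**Where is "the reward"?** The zone start sits at a fixed offset from the
landmark within a trial type, so aligning to the zone start is a rigid
shift of landmark alignment — the two mean traces have identical peaks and
cannot be distinguished. What distinguishes reward-anchored activity is the
*per-trial variability of the actual reward event* (the location of the
rewarded lick, which moves around inside the zone from trial to trial).
The default is therefore `rewardRef = "event"`: alignment to the trial's
recorded reward-delivery location, falling back to the zone start where no
event exists (decoupled sessions). `rewardRef = "zone_start"` is available
for sensitivity analyses; under it, landmark/reward assignment ties are
expected, flagged, and broken by the fixed priority landmark > reward >
trial onset.

Aligned activity is binned into half-open bins `[lo, lo + w)` with edges at
integer multiples of the bin width (5 cm for population analyses and
classification, 2 cm for spatial transient detection), averaging all frames
in a bin (occupancy-weighted mean). Because starts are randomized, edge
bins are visited by few trials; a bin enters an across-trial mean only when
at least 50% of trials cover it. With uniform 50–150 cm starts this places
the first usable landmark-aligned bin near −100 cm.

# Behavioral metrics

The **task score** is `median(first lick, long) − median(first lick,
short)` in landmark-aligned cm (midpoint convention for even counts). First
licks count anywhere on the corridor; lickless default-reward trials are
excluded from lick statistics but stay in success-fraction denominators.
An expert licking at a fixed landmark distance scores near 60 cm (the
offset difference); random licking scores near 0.

The **spatial modulation z-score** asks whether reward triggering depends
on lick placement. The statistic is the fraction of trials with ≥ 1 lick
inside the zone; the null rotates each trial's lick positions circularly by
an independent uniform offset and recomputes the session fraction 1000
times; `z = (true − mean(null)) / sd(null)`. The rotation support is the
trial's full operant extent, from the start through the reward-zone end
(or the traversed extent if longer). Using the traversed extent alone would
be biased: successful trials teleport at the rewarded lick, so their
traversal ends *inside* the zone, the null under-samples the zone, and even
a random licker would score systematically positive. With the operant-extent
support the package's calibration suite measures a random-licker mean z
near 0 with unit spread, while expert policies separate by z > 3
essentially always.

The **start vs first-lick regression** is ordinary least squares in raw
track coordinates. It requires variance in start locations — which is why
raw storage keeps the landmark fixed and the start randomized rather than
re-zeroing each trial — and distinguishes landmark-guided licking
(slope ≈ 0) from an internal odometer (slope ≈ 1).

# ΔF/F and transients

`computeDff()` subtracts neuropil where available and divides by a baseline
`F0(t)`, the 5th percentile (somata; 50th for boutons, whose baselines are
a larger share of the trace) of the signal in a centered 60 s window,
truncated at the edges. Non-positive baselines are an error naming the
offending frames; the transform is exactly invariant to common positive
rescaling of raw and neuropil.

Transients are threshold crossings of ≥ 6 standard deviations of the
neuron's *baseline activity*, defined as the lowest 70% of its ΔF/F
samples; measuring spread over the baseline sample rather than the full
trace keeps the threshold from inflating with the neuron's own signal, and
referencing the baseline mean makes detection invariant to constant
offsets. In time, a transient must stay above threshold for ≥ 500 ms
(converted to frames by ceiling: 8 frames at 15.5 Hz); in anchor-aligned
space, for ≥ 2 consecutive 2 cm bins, and spatial transients farther than
±60 cm from the neuron's mean-trace peak are discarded. Detection uses a
hysteresis release level of 2 baseline s.d.: an event extends while the
signal stays above the release level, and isolated unvisited bins extend
(but never qualify) an event. Without this, the decaying GCaMP6f tail
hovering near threshold — or a single 2 cm bin skipped at high running
speed — splits one event into several and roughly doubles counts; with it,
the generator's per-trial event truth is recovered exactly in the
parameter-recovery suite. *Jitter* is the standard error of transient-peak
distance from the mean peak; *robustness* is the fraction of trials with an
in-window transient.

# Classification

A neuron is task engaged on a trial type when all four criteria hold: more
than 0.5 transients/min over the session; ΔF/F above 3 s.d. of the ROI's
overall (full-session) activity on ≥ 25% of trials; a shuffle peak z-score
above 3; and mean-trace amplitude (max − min) above 0.2 ΔF/F (0.1 for
boutons). The shuffle null circularly shifts the ΔF/F series relative to
behavior (preserving autocorrelation, so slow calcium kinetics do not
inflate z) with a minimum shift of 10 s to avoid near-identity shuffles,
500 times by default.

The anchor category is the alignment maximizing the mean-trace peak.
`classifySession()` reports it per trial type, and additionally pooled over
both types. Pooling is the stronger discriminator of landmark- versus
reward-anchored cells: within one type the two anchors differ only through
reward-event scatter (a few cm), while across types the reward sits at
120 vs 180 cm from the landmark onset, so the wrong alignment smears into
two separated modes. In pooled mode a bin must reach 50% coverage within
*each* trial type; otherwise regions traversed by only one type (past the
short-trial reward) would escape cross-type averaging and bias the
comparison. Exact peak ties are broken landmark > reward > trial onset and
flagged. The landmark modulation index of landmark cells,
`(LM_short − LM_long)/(LM_short + LM_long)`, uses the per-type peak means.

# Trial-type decoding

The template decoder represents each trial as the vector of its neurons'
single-trial responses — the peak of the aligned, binned (5 cm) trial trace
within ±20 cm of the neuron's classified peak location, the same amplitude
convention used for condition comparisons; the per-window mean is available
as an alternative. Negative values are kept (no rectification). Templates
are per-type means; similarity is the cosine
`Θ_θ = Σ_i R_i^t R_i^θ / (‖R^t‖ ‖R^θ‖)`; the decoded type is the argmax,
with exact ties broken randomly under the stage seed and counted. The
default holdout is leave-one-out — the decoded trial is excluded from its
own template — because an all-trials template is optimistically biased at
small trial counts; the all-trials mode is provided for comparison. With
leave-one-out, a noiseless fully selective population decodes exactly 1.0,
and a selectivity-free population is statistically at chance.

# Population vectors and reconstruction

Trials are split randomly in half (half A takes the extra trial when odd).
Each neuron's activity is binned at 5 cm per half under the coverage rule,
averaged, and normalized to its own maximum; half A also fixes the
neuron's peak bin for ordering population plots, so that peak placement and
displayed activity come from independent data. The cross-correlation matrix
correlates (Pearson, across neurons) the half-A vector at bin *i* with the
half-B vector at bin *j*; bins supported by fewer than 2 neurons are
missing for that split; the matrix is averaged over 10 independent splits.
The reconstruction error takes, per split and per row (actual location),
the distance in cm to the argmax column — ties resolved toward the actual
location, which is the conservative choice — then averages over rows and
splits; all-missing rows are skipped with a warning. Errors between
alignments are compared on the same trial type with the same split seeds.
In the fully deterministic limit (fixed start, constant speed, noise-free
traces, vanishing tuning width) the two halves are identical and the error
is exactly zero, which the test suite asserts.

# Decoupled-condition analyses

In the decoupled ("open-loop") condition the corridor flows at fixed 10 and
30 cm/s regardless of the treadmill, no rewards are given, and the animal
is free to run or rest. The condition response of a neuron is measured at
its VR peak location, allowing a ±20 cm window for receptive-field shifts.
Trials are labeled running when mean treadmill speed within ±50 cm of the
neuron's peak (in corridor-flow coordinates) strictly exceeds 3 cm/s —
boundary cases are resting — and a neuron needs ≥ 3 trials of each label.
Black-box responses are read at the single frame nearest 1.5 s after
black-box onset (the convention specifies an instant, not a window), with
locomotion judged within ±1 s of that instant. The supralinearity test
compares `landmark+motor` against `landmark-only + motor-only` per neuron
(components may be negative; no clipping) and calls the population
supralinear by a one-sided paired Wilcoxon signed-rank test at p < 0.01;
per-neuron differences are the primary output, the p-value secondary.
Running-speed/amplitude correlations use the mean speed during each
transient against its peak, requiring ≥ 10 transients.

# The synthetic-session generator

`generateSession()` is first-class, tested code, not a fixture. It renders:

- **Behavior.** Running speed is a bounded AR(1) process (mean 20 cm/s,
  clamped to 5–45 cm/s) integrated into position; black boxes last 3 s plus
  up to 0.5 s. Licking policies: *expert* places the first lick at the
  reward-zone start + N(8, 6) cm followed by a short bout; *naive* scatters
  widely around the zone; *random_licker* licks as a spatial Poisson
  process (0.05/cm) with no spatial knowledge; *odometer* licks a fixed
  200 cm after the start. Licks are assigned to the nearest frame, and
  success/reward are then decided from the *recorded* lick positions, so
  the stored behavior is self-consistent under frame quantization.
- **Neurons.** Each transient is placed in distance-from-anchor space
  (Gaussian jitter of s.d. `width_cm` around `pref_dist_cm`; occurrence
  Bernoulli with `p_transient` per trial), mapped to a frame through the
  trial's position series, and rendered as amplitude × exponential decay
  (τ = 0.6 s, approximating GCaMP6f offset kinetics) on a zero baseline
  with i.i.d. Gaussian noise (s.d. 0.1 ΔF/F). Reward-anchored neurons
  anchor to the trial's actual reward event. Trial-type selectivity scales
  amplitudes by `(1 ± lmi_target)`. Visuo-motor integration is either
  multiplicative (`p_transient × motor_gain` while locomoting) or additive
  (a tonic ΔF/F offset while locomoting).
- **Decoupled condition.** Corridor flow alternates 10/30 cm/s; treadmill
  locomotion is an independent exponential on/off bout process (8 s mean
  bouts, ~15 cm/s running) — no locomotion statistics are reported for this
  condition, so these are declared generator choices, not fits.

One seed determines everything; per-neuron sub-seeds are derived
deterministically, so a neuron's trace does not depend on how many neurons
are simulated and matched VR/DC pairs share neuron identities.

What the generator does *not* emulate — and what passing tests therefore do
not show about real recordings: photon/shot noise and motion artefacts,
bleaching, spike-to-fluorescence nonlinearity beyond the single decay
kernel, multi-peaked or sustained fields, correlated noise across neurons,
behavioral learning within a session, and reward-anticipatory licking
structure beyond the first-lick policies.

# Validation problem sizes

The acceptance suite (mirrored by `scripts/acceptance.R`) runs: 200
random-licker and 60 expert 40-trial sessions for SMZ calibration
(1000-shuffle nulls); 300 neurons (100 per anchor, p = 0.6, width 8 cm) for
category recovery plus 100 noise-only ROIs for the engagement
false-positive rate (500-shuffle z); decoder calibration on 200 agnostic
trials, a noiseless selective population, and a |LMI| = 0.5 population;
20-seed orderings of reconstruction error (landmark vs onset; VR vs a
decoupled degradation with p ÷ 3 and width × 2) with a 36-neuron population
tiling −100…140 cm; a 200-trial transient-recovery session (p = 0.45,
width 8); and 20 additive and 20 multiplicative integration pairs. These
sizes give 3-s.e. recovery bands and ≥ 19/20 ordering checks while keeping
the suite fast.

# Known limitations

Per-trial-type landmark/reward assignment is intrinsically weak when reward
events are stereotyped (it rests entirely on reward-event scatter); use the
pooled category where possible. The reconstruction error is meaningful only
where the population tiles space — rows outside the tuned span reconstruct
arbitrarily and are reported but dominated by edge noise. The SMZ assumes
the zone is reachable within each trial's rotation support. The
sliding-percentile baseline is O(frames × window) per ROI; for very long
sessions compute ΔF/F once and store it in the container.
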