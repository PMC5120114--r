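---
title: "Methods: co-registered eye-tracking and EEG analysis of attention shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-registered eye-tracking and EEG analysis of attention shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazerp)
```

## The experimental design this package analyses

`gazerp` implements the analysis pipeline for a fixation-shift experiment in
which adults either *overtly* shift attention — making a saccade from a
central fixation dot to a peripheral target — or *covertly* shift attention,
holding fixation and pressing a button on the side of the target. Targets
appear at 12.9° eccentricity on the left, the right, or on both sides
(double-target trials force a choice and carry a decision cost on response
latency). Gaze is recorded with a remote 60 Hz eye tracker, EEG with a
128-channel geodesic net at 250 Hz, and the two streams are co-registered:
the eye tracker both drives the gaze-contingent stimulus (targets appear
only after a stable central fixation) and, post hoc, *gates* the EEG so
that only epochs free of early eye movements contribute to event-related
potentials (ERPs). The scientific point of the gating is that the analysis
window (−200…180 ms around target onset) then precedes the saccade on
essentially every retained trial, so overt-shift ERPs can be compared with
covert-shift ERPs without ocular artifact correction.

Each session comprises two response blocks of 400 trials (manual block
first, so saccade habits are not carried into the fixation-holding task),
with 100 left, 100 right and 200 double targets per block and inter-trial
intervals drawn uniformly from 0.5–2.5 s.

## Gaze processing

**Repair.** Missing tracker samples are filled, in temporal order, with the
mean of the previous sample (possibly itself repaired) and the next valid
sample; runs of missing samples apply the rule repeatedly. Leading and
trailing gaps have no bracketing samples and stay invalid. This operator is
idempotent and never alters valid samples (both tested).

**Online detectors.** Central fixation requires ≥ 20 consecutive samples
(~330 ms) with Euclidean dispersion strictly below 2.6° of the fixated
object; target acquisition requires 20 consecutive samples inside an
8° × 8° box around the target. Both are run-based with strict inequality
at the dispersion boundary.

**Saccade onset.** The onset is the sample *before* the first horizontal
position change exceeding 2.2° between successive samples — at 60 Hz a
velocity criterion of 132°/s. Only the horizontal component is used, and
interpolated samples participate (repair precedes analysis).

**Trial classification.** Exclusion rules apply in a fixed order, first
match wins, so reported fractions are unambiguous: (1) gaze off screen at
target onset (tolerance box ±19.6° × ±11.0°, which brackets the physical
screen); (2) noisy tracking — more than 20% of successive-sample
displacements above 2.2°, computed over the whole trial trace; (3)
anticipatory responses earlier than 0.1 s; then sticky fixations (no
response within 5 s) and misdirected responses (single-target trials whose
first suprathreshold step, or button press, went to the wrong side).
Valid-correct trials carry the raw latency (response onset − target
onset); raw latencies are used for condition comparisons because constant
tracker delays cancel in differences. Manual-block trials use the logged
button press as the response event while any detected saccade is still
recorded — it marks a fixation break, which matters for gating below.

**Timing corrections.** The tracker pipeline delays gaze by ~30 ms and the
display refresh adds up to one frame (16.7 ms; 8.3 ms on average). These
delays matter only where eye-tracking feeds the EEG analysis, so a single
fixed 50 ms correction is subtracted from measured saccade latencies when
gating epochs; it deliberately over-covers the mean total delay so that no
true saccade can slip inside the analysis window.

## EEG processing

Continuous data pass through three zero-phase Butterworth filters
(band-stop 49–51 Hz, high-pass 0.01 Hz, low-pass 25 Hz). The order is 4;
forward–backward application makes the cascade phase-free, which protects
peak *latencies*, the quantity the analysis reports. We verified the
band-stop attenuates a 50 Hz probe by ≥ 95% while a 10 Hz probe is
preserved within 5%. An average reference is applied, and epochs of
−200…180 ms (half-open grid, 95 samples at 250 Hz, t = 0 at target onset)
are cut after shifting every event 24 ms later on the EEG timeline — the
measured amplifier group delay; the synthetic generator emulates the same
delay so the correction is observable end to end.

**Robust screening.** For every (channel, epoch) pair four noise metrics
are computed on baseline-uncorrected data: SD over samples, amplitude
range, drift (|mean post-onset − mean pre-onset|), and maximum
successive-sample step. For each metric an upper threshold
median + 3 × 1.483 × MAD is estimated from the values pooled over all
(channel, epoch) pairs of the session — the 1.483 factor makes the MAD a
normal-consistent spread estimate, and one-sided flagging reflects that
all four metrics are noise magnitudes. A channel is clean in an epoch iff
no metric exceeds its threshold *and* its SD exceeds 0.1 µV (a flat
electrode received no signal; a zero MAD flags nothing by construction).
An epoch is kept iff strictly more than 70 of the 128 channels are clean.

**Channel repair.** Non-clean channels of kept epochs are reconstructed by
spherical-spline interpolation (stiffness m = 4, 20 Legendre terms, unit
spheres from the layout file) from the epoch's clean channels, then
re-checked once against the same thresholds; channels still failing stay
excluded from cluster averages. The spline reproduces constant fields
exactly and degree-1 spherical harmonics within 5% at interior channels
(tested against closed forms and leave-one-out).

**Baseline.** The mean over the pre-onset samples ([−200, 0) ms; whether
t = 0 itself belongs to the baseline changes the mean by less than one
sample and we adopt the half-open convention) is subtracted per trial and
channel.

## Gaze-gated ERPs

Epochs whose corrected saccade latency (measured latency − 50 ms) falls
below 180 ms are excluded in *both* blocks: a manual-block trial with a
detected fixation break is treated exactly like a saccade trial, since the
contamination is the same. The pipeline asserts, over the QC log, that no
retained epoch violates this bound.

ERPs are measured on electrode clusters: occipital O1/O2 (EGI channels
65, 66, 70, 71, 69, 74 and 90, 84, 76, 83, 82, 89), frontocentral FC3/FC4
(12, 13, 19, 24, 20, 28, 29 and 4, 5, 111, 112, 117, 118, 124), and
prefrontal FP1/FP2 clusters formed from the channels nearest the
frontal-pole positions of the shipped layout (the ids are configurable
because no standard fixes their membership). Waveforms average cluster
channels, then epochs (the order is immaterial by linearity; fixing it
makes QC logs reproducible). Peaks are the windowed extrema — positive
polarity for the occipital positivity and prefrontal positivity, negative
for the frontocentral negativity — with ties resolved to the earliest
sample. The occipital and frontocentral search window is 80–180 ms,
chosen to bracket the ~141/~136 ms peaks these components show while
excluding early noise; the prefrontal window is the conventional 120–180 ms for this component.
Condition cells cross response type × number of targets × hemisphere
(ipsi/contralateral to the responded side — for double targets the side
actually responded to) × brain side.

Descriptive condition tables report mean, SD and n, and effect sizes use
pooled-SD Cohen's d, |M₁−M₂| / √((SD₁² + SD₂²)/2); this variant reproduces
the reference behavioural (d = 2.317) and amplitude (d = 0.457) worked
examples from their rounded group statistics. A
paired-difference d would need subject-level pairing that single-session
data do not provide, so it is not offered.

## The synthetic-session generator

Raw recordings for this paradigm are not publicly deposited, so the
package ships a generator that emulates a session of the same design and
logs its ground truth; every downstream stage is validated against that
truth.

* **Latencies** are shifted lognormal (shift 80 ms — giving the right skew
  of empirical saccade latencies) with cell means 0.296/0.320 s (saccade,
  single/double) and 0.468/0.492 s (manual), i.e. the reference marginal
  means 0.308 and 0.480 s split by the reference 0.024 s double-target
  cost, with marginal SDs 0.038 and 0.098 s. Anomalies are injected with
  small probabilities (0.5% each: anticipatory, sticky, misdirected), and
  2% of gaze samples are dropped to exercise the repair rule.
* **Gaze traces** jitter around fixation (SD 0.3°) and, in the saccade
  block, ramp to ±12.9° over 3 samples at the injected latency — a linear
  ramp is adequate because only the onset is consumed downstream.
* **EEG** sums three Gaussian-time-course components (occipital positivity,
  frontocentral negativity, and a prefrontal positivity present only in
  manual-response and double-target cells), a lateralized frontal
  step-plus-transient saccade artifact starting at the injected saccade
  onset in saccade-block trials, 1/f background (spectrally shaped),
  white sensor noise with per-channel lognormal gain spread, a common
  50 Hz line component, and three bad channels overwritten with
  high-variance noise. Component scalp maps are Gaussian fields centred
  on the cluster anchor sites, lateralized (contralateral weight 0.7) for
  single targets, and linearly mixed so that each component's
  average-referenced map has unit mean over its own cluster union and
  zero mean over the other components' unions. This idealization — real
  source geometry is unknown — makes every injected amplitude directly
  identifiable from cluster waveforms, which is what turns the generator
  into a quantitative test harness. Maps are centred over the channels
  that actually carry signal so the pipeline's average reference does not
  re-introduce leakage from the bad channels.
* **Determinism.** A single master seed spawns per-trial substreams, so any
  trial can be regenerated in isolation and identical seeds give
  byte-identical session files.

**Default SNR.** Noise levels (white 1.0 µV, pink 1.4 µV RMS per channel,
line 10 µV) were chosen once, on two grounds. First, screening thresholds
must be *noise*-dominated: robust MAD cutoffs estimated from data in
which the ERP itself is the largest per-epoch deviation would flag the
very channels carrying the signal — with these levels the cutoffs sit
several noise-MADs above any injected component, as in real recordings
where single-trial EEG noise dwarfs a 1–2 µV ERP. Second, condition-cell
averages of ~200 epochs × ~12 cluster channels must resolve a 0.83 µV
amplitude to better than 10%, which bounds the usable noise from above.
Real EEG is noisier than this; the generator is a validation instrument,
not a realism benchmark, and passing recovery tests here demonstrates
correctness of the pipeline's book-keeping and numerics, not expected
performance on empirical data.

**What the generator does not emulate:** vertical saccades and
microsaccades, smooth pursuit, blinks, pupil dynamics, spatially
correlated cortical noise, non-stationary impedance drifts, and the
phase-reversing bar stimulus itself. Tests passing on synthetic sessions
therefore say nothing about, e.g., blink-artifact behaviour on real data.

## Numerical choices and edge cases

* Epoch grid: half-open [−200, 180) ms, 0-based offsets, 95 samples; the
  t = 0 sample belongs to the post-onset segment for the drift metric.
* Filters are applied per channel in transfer-function form; we verified
  the 0.01 Hz high-pass is numerically stable at order 4 and that
  linearity holds to ~10⁻⁴ relative (rounding is amplified by the
  near-unit-circle poles; the test bounds it explicitly).
* MAD = 0 (degenerate spread) flags nothing; fewer than 5 pooled values
  is an error rather than a silent pass.
* Peak ties resolve to the earliest sample; empty condition cells return
  explicit empty results, never zeros.
* Saccade onsets are reported as the sample *before* the first
  suprathreshold step, so measured saccade latencies underestimate the
  movement onset by up to one 60 Hz sample (half a sample, 8.3 ms, on
  average); recovery comparisons against generator truth remove this
  deterministic sampling offset, while reported latencies keep the raw
  convention because empirical latencies measured with the same rule
  carry the same offset.
* Off-screen rule: the stated tolerance box exceeds the physical
  screen half-width, so it is treated as a tolerance box on |x|, |y|.
* "At least 20" (central fixation) vs "more than 20" (acquisition)
  samples are both implemented as ≥ 20 for consistency.
* The misdirected rule tests the *first suprathreshold step's* sign, and
  the noisy-trial fraction is computed over the whole trial trace; both
  points are ambiguous in the source description and are implemented as
  stated here.
* Whether rejected channels should be re-screened against thresholds
  recomputed after interpolation is under-determined; a single recheck
  pass against the session thresholds is used.
* Manual-block trials with a detected fixation break are excluded from
  ERP cells (not merely noted); the gate treats both blocks identically.

## Problem sizes used in validation

Unit tests run on sessions of 5–40 trials; the end-to-end recovery suite
uses one full-size session (400 trials per block, ~1900 s of 128-channel
EEG) and checks: behavioural cell means within 3 SE of generator means;
occipital peak latency within one EEG sample (4 ms) and amplitude within
10% per condition cell; bad-channel screening sensitivity ≥ 0.9 with
false-flag rate ≤ 5%; zero gating violations; and byte-identical repeat
runs under a fixed seed. With all noise and anomalies disabled the
pipeline recovers injected response latencies to one 60 Hz sample and ERP
peak latencies to one 250 Hz sample.

## Known limitations

* The shipped electrode layout is synthetic (vendor geodesic coordinates
  are not redistributable); cluster membership for O/FC clusters is by
  fixed channel id, so only the FP clusters and the spline geometry
  depend on it. Supplying a real layout TSV transparently replaces it.
* The pipeline analyses one session at a time; multi-subject inference
  (mixed models, Bayes factors) is out of scope by design.
* The analysis window ends at 180 ms, so late components (e.g. P300) are
  inaccessible by construction.
* EEG I/O uses raw float32 + JSON sidecar; EDF import is not provided.
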