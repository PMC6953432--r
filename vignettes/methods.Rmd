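---
title: "Quantifying discontinuous neonatal cortical activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying discontinuous neonatal cortical activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(neonosc)
```

## The scientific problem

In the first two postnatal weeks, the rodent prefrontal cortex does not
produce continuous network activity. Instead, the local field potential (LFP)
alternates between long stretches of electrical silence and spindle-shaped
oscillatory events that mix a slow theta (4–12 Hz) component with faster
beta–gamma (12–100 Hz) components. The spiking of individual neurons is timed
by these oscillations, and both the oscillations and the spike–field
relationship differ between healthy animals and disease models (here: a
dual-hit genetic–environmental, "GE", model combining a DISC1 mutation with
maternal immune activation, plus a minocycline-treated rescue group,
"GE_mino"). Parallel immunohistochemistry quantifies microglia — their number,
shape, and how much presynaptic VGLUT1 material they have engulfed — because
microglial over-pruning of synapses is the proposed mechanism linking the
model to the electrophysiological phenotype.

`neonosc` implements the full quantification chain for this kind of study:

1. **preprocessing** — zero-phase Butterworth filtering into analysis bands,
   integer decimation, common-average rereferencing;
2. **event detection** — unsupervised segmentation of the LFP into
   oscillations and silence from an RMS envelope with a Gaussian-fit
   threshold;
3. **spectra** — Welch power restricted to oscillatory windows, band powers,
   and a bounded modulation index for optogenetic ramp stimulation;
4. **spiking** — multi-unit spike detection from the 500–5000 Hz band, firing
   rates, inter-spike-interval (ISI) distributions;
5. **spike–field coupling** — pairwise phase consistency (PPC) and
   spike-triggered relative LFP power;
6. **morphometry** — microglia counting, 2D shape features, 3D hysteresis
   segmentation, VGLUT1 puncta detection and engulfment;
7. **robust statistics** — Yuen-type trimmed-mean bootstrap tests and a
   heteroscedastic trimmed-means one-way ANOVA;
8. **classification** — a repeated cross-validated k-nearest-neighbors
   pipeline over per-animal features, with held-out group prediction and a
   t-SNE decision map;
9. **synthetic data** — generators for every input above with stored ground
   truth, so the whole pipeline is testable without animal data.

Because the original cohort-level numbers derive from real recordings and
images, the package's validation is property-based: every quantitative claim
in the test suite is checked against planted ground truth, an analytic value,
or an independent brute-force oracle.

## Signal path and conventions

All signals are numeric vectors in microvolts with an explicit sampling rate.
Filtering is zero-phase (third-order Butterworth run forward and backward,
with reflect padding of at least three filter lengths) so that phases and
event boundaries are not displaced; the standard bands are 4–100 Hz for LFP
analysis, 1–100 Hz for event detection, and 500–5000 Hz for multi-unit
activity (MUA). Wide-band acquisitions at 32 kHz are decimated to 3.2 kHz for
LFP work after band-limiting; the 4–100 Hz band-pass alone provides the
anti-alias margin, so no separate low-pass stage is inserted. With more than
one channel, common-average rereferencing subtracts the across-channel mean
at every sample, cancelling shared movement artifacts exactly.

Band edges follow a half-open convention `[lo, hi)` everywhere (theta 4–12,
beta 12–30, gamma 30–100 Hz), so adjacent bands never double-count an edge
frequency; band power is the left-closed Riemann sum of the one-sided PSD,
which makes disjoint bands exactly additive.

## Event detection

The detector follows the classical unsupervised recipe for neonatal
oscillations: a sliding RMS envelope of the 1–100 Hz signal (200 ms window —
long enough to smooth gamma cycles, short against the 1-s minimum event),
thresholded at `mu + k * sigma` of a Gaussian fitted to the envelope
histogram restricted to the range from 0 up to the histogram's peak. This
restriction is the key robustness device: event samples populate the right
tail, silence the mode, and fitting only the left flank estimates the silence
distribution uncontaminated by events. The fit is nonlinear least squares on
bin centers (amplitude, mean and SD free); when strong events stretch the
histogram so far that the silence mode occupies too few bins, the histogram
is re-binned finer until the left flank is resolved. Both readings of the
phrase "global maximum of the histogram" are available (`mode_def = "mode"`,
the peak bin, is the default; `"max"` uses the full range).

Supra-threshold intervals closer than 200 ms are merged into a single
oscillation *before* the duration rule discards anything lasting 1 s or less
(merge-then-filter). `k = 2` is the default threshold multiplier; it is the
single most result-sensitive free parameter of the detector, is exposed in
the interface, and raising it can only decrease the number of detections (a
tested invariant).

A centered RMS window smears boundaries outward by up to half its length
(the window "sees" the event before it starts). The detector therefore
re-localizes each interval's onset with a causal (trailing) window and its
offset with an anti-causal (leading) window at the same threshold — these
cross close to the true power step, with a small SNR-dependent delay —
before merging. On default-SNR synthetic recordings this puts the median
absolute boundary error near 50 ms; the *mean* error is larger because a few
events legitimately merge with adjacent supra-threshold noise excursions
under the 200-ms rule, extending one boundary.

## Spectra of oscillatory activity

Because silence dominates neonatal recordings, power spectra are computed
only over oscillatory windows: each detected event contributes
`floor(duration)` non-overlapping 1-s windows, and Welch's method (Hann
taper, no overlap, 1-Hz resolution) averages over all of them. The one-sided
densities are scaled so that the integrated PSD reproduces the signal
variance (a tested Parseval identity).

For optogenetic ramp sessions, band power in the 1.5 s before stimulation is
compared with the last 1.5 s of the ramp (two 0.75-s Hann segments per
window), summarized by the bounded modulation index
`(stim − pre) / (stim + pre)`. The symmetric bounded form is the field's
standard contrast; it is reported as `NA` when both powers are zero, equals
0 for no modulation and 1 when power exists only during stimulation, and is
invariant under global amplitude rescaling.

## Spike detection and ISI statistics

MUA spikes are the peaks of negative deflections of the 500–5000 Hz signal
exceeding five standard deviations, kept only if their prominence (standard
peak analysis on the inverted trace) exceeds half the peak amplitude. The SD
is the plain standard deviation of the full trace by default, matching the
protocol; a median-based robust estimate is available behind a flag because
heavy spiking inflates the plain SD. A 1-ms dead time prevents multiphasic
waveforms from being counted twice. Detection is invariant to amplitude
rescaling, recalls planted −10 SD spikes essentially completely at densities
up to 20 spikes/s, and produces fewer than 0.05 false events per second on
pure Gaussian noise.

ISI histograms use 2-ms bins; the mass is normalized by the *total* number
of intervals, while only the 10–500 ms range is returned — so the returned
mass sums to less than 1 whenever intervals fall outside the display range
(a convention the tests pin down with regular 60-ms and 600-ms trains). The
60-ms preferred interval of frequency-tuned superficial pyramidal neurons
corresponds to a 16.7-Hz population rhythm.

## Spike–field coupling

**Pairwise phase consistency.** Band phase is the angle of the analytic
signal (FFT Hilbert construction) of the zero-phase band-passed LFP — the
phrase "extracted as mentioned above" in protocol descriptions of this
statistic is interpreted as this standard construction; phase 0 sits at
oscillation maxima. PPC is the mean cosine of all pairwise phase
differences, computed through the closed form
`(|Σ e^{iθ}|² − n) / (n(n−1))`, which the test suite verifies against
brute-force pairwise summation to 10⁻¹⁰. Unlike the resultant length, PPC
has no sample-size bias; its population value under von Mises locking with
concentration κ is `(I₁(κ)/I₀(κ))²`, and the estimate recovers this within
±0.02 at 2000 spikes for κ ∈ {0, 1, 2, 4}.

**Spike-triggered relative power.** For each spike,
`(P_spike − P_baseline)/P_baseline` per frequency, where `P_spike` is the
Welch power of the 200-ms window centered on the spike and `P_baseline`
averages the spectra of the two windows 100–300 ms and 200–400 ms before it
(the windows overlap by construction; their PSDs, not their samples, are
averaged). Per-spike ratios are averaged, matching the formula's placement
inside the spike loop; band summaries average the curve over beta and gamma.

One numerical point deserves emphasis. A power estimate in a denominator is
inverse-chi-square distributed, so the ratio is biased upward by
`ν/(ν−2)`, where ν is the baseline's effective degrees of freedom. With one
200-ms periodogram per window the baseline has ~4 dof and the *expected*
relative power under the null is exactly 1 — useless. The estimator
therefore (i) averages 40-ms Hann segments at 50% overlap inside every
200-ms window (zero-padded so values are still reported on a 5-Hz grid),
giving the baseline ~24 effective dof, and (ii) applies the exact
`(ν−2)/ν` correction, with ν computed from the Welch segment geometry
(Percival–Walden effective-dof formula) and the half-overlap of the two
baseline windows. Under the null the mean relative power is then within
±0.01 of zero. The price is 25-Hz spectral resolution — the physical limit
of a 200-ms window with within-window averaging — so peak locations are
meaningful to one resolution step, and the DC bin (suppressed by
per-segment demeaning) is not reported.

## Microglia morphometry

Counting reproduces the standard macro chain: maximum-intensity projection,
3×3 median despeckle, Gaussian blur (σ = 2 px), triangle-method automatic
threshold, connected components strictly larger than 150 px. The triangle
threshold operates on the histogram between the data minimum and maximum,
which makes the count invariant to global affine intensity rescaling (a
tested property). Note that the size gate applies to the *processed*
component — blurring plus a low automatic threshold inflates a bright sharp
object beyond its native pixel count — so for synthetic binary blobs the
effective native-size cutoff sits below 150 px.

For 2D morphology, a global Otsu threshold segments the projection;
components of 200–1500 px are candidate cells; a 110×110 px region of
interest is centered on each centroid, and cells touching the ROI border,
whose ROI leaves the image, or sharing their ROI with another component are
discarded (the automated counterpart of the protocol's visual exclusion;
the size gate is applied before the ROI rules). Features per cell:

* **area** and **perimeter** — the perimeter uses a chain-code walk with the
  Vossepoel–Smeulders correction (0.980 per axial step, 1.406 per diagonal
  step, −0.091 per corner). Naive pixel-edge counting biases roundness by
  over 20%; with the corrected estimator a rasterized disc of radius 40 px
  scores roundness ≈ 1.01 and a large square ≈ 0.83 against the analytic
  π/4 ≈ 0.785 — the residual square bias is the known cost of an estimator
  tuned for smooth outlines.
* **roundness** — `4π·area / perimeter²`.
* **eccentricity** — from the equivalent-ellipse second moments (a 4:1
  ellipse scores √(1−1/16) ≈ 0.968 exactly).
* **spread** — the mean distance from the center of mass to the 8 extremal
  boundary points (the classical region-analysis "extrema" convention), a
  proxy for process length.

For engulfment, the microglia channel is segmented by 3D hysteresis
(seeds at ≥ 0.5 of the intensity range, extension to ≥ 0.1 through
26-connectivity) followed by a 3×3×3 median filter. The VGLUT1 channel goes
through rolling-ball background subtraction, despeckle, a 2-px maximum
filter, Otsu binarization, per-plane watershed splitting, 3D labeling
(8-connectivity in plane, direct voxel overlap across planes — using the
full dilated neighborhood across planes would undo the watershed splits),
and a 100–500 voxel size gate. Two implementation notes: the rolling-ball
footprint is four times the nominal 2-px radius (the classical rolling-ball
implementation's contact patch likewise spans several times its nominal
radius; with a literal 2-px footprint the estimated background reproduces
the puncta themselves and subtraction would erase them), and the binarized
maximum-filtered stack is eroded by the same 2-px element, making
max-filter → threshold → erosion act as a morphological closing so that
measured volumes refer to the native punctum scale (planted volumes are
recovered within ~10%).

A punctum is engulfed only under 100% overlap: every voxel inside the
processed cell mask; one voxel outside disqualifies it. On planted fixtures
the engulfed count is recovered exactly. Distal cell volume sums mask
voxels at physical distance ≥ 7 μm from the center of mass, with
anisotropic calibration (defaults 0.103 μm pixel, 0.75 μm z-step); a
rasterized 10-μm sphere reproduces the analytic 7–10 μm shell volume to
0.02%.

## Robust group statistics

All group comparisons use 20% trimming. The building blocks are the trimmed
mean (drop `floor(0.2 n)` values from each tail) and the winsorized
variance (clamp to the trim quantiles, then the usual variance). Yuen's
two-sample statistic divides the trimmed-mean difference by the winsorized
standard error; the paired variant applies the same machinery to difference
scores; the one-way statistic is the Welch-type heteroscedastic F for
trimmed means. Null distributions come from bootstrap-t resampling of
groups centered at their own trimmed means (5000 repetitions by default),
with the symmetric two-sided p-value smoothed by +1 in numerator and
denominator so p = 0 cannot occur; confidence intervals for trimmed-mean
differences are percentile-bootstrap. Under Gaussian nulls the empirical
type-I error at α = 0.05 calibrates into [0.03, 0.07] for both the
two-sample and the one-way test (1000 simulations × 1000 resamples in the
test suite — scaled down from the 5000 production repetitions purely for
suite turnaround; the calibration is insensitive to this). Pairwise
post-hoc contrasts are emitted without additional multiplicity correction;
the choice of correction is left to the caller. Linear mixed-effects models
and ANCOVA, used for nested designs, are deliberately not re-implemented —
the tidy outputs feed `lme4`/`car` directly.

The behavioral discrimination ratio is
`(t_novel − t_other)/(t_novel + t_other)`, bounded in [−1, 1], `NA` when
the animal never interacted; the same formula serves single-interaction
ratios.

## Phenotype classification

Per-animal feature vectors (by default five: beta and gamma LFP power,
log10 firing rate, and spike-triggered relative power in beta and gamma,
all from superficial layers; behavioral tables use discrimination ratios
and single-interaction times) feed a repeated cross-validation scheme: 500
iterations (100 in the scaled-down acceptance runs) of stratified 2/3–1/3
splits; on each training set an inner stratified 3-fold grid search tunes a
pipeline of quantile transformation (to a uniform output; the number of
landmark quantiles is tuned over {5, 10, 25}), mutual-information feature
selection (percentile over {40, 60, 80, 100}; MI estimated by
equal-frequency discretization), and kNN classification (neighbors
{1, 3, 5, 7}, uniform or inverse-distance weights, Euclidean metric after
transformation). The held-out third scores each iteration; the reported
figure is the median accuracy. Two deliberate deviations from a literal
hyper-parameter list: stratification is imposed on the outer splits (at
n ≈ 30 animals unstratified splits regularly produce one-class folds), and
the search-tree leaf size is excluded from the grid because exact
neighbor search cannot change predictions, only speed. Ties in distance
resolve to the smallest training index and ties in votes to the first
class level, making every run reproducible from the master seed alone.

All per-iteration fitted pipelines are retained as an ensemble. A held-out
cohort (e.g. the rescue group) is classified by majority vote across the
ensemble, reported per animal (vote fraction) and per group (fraction of
animals assigned to each class). The decision map embeds the cohort with
t-SNE (perplexity adapted to cohort size, exact gradient) and colors a
dense grid by 1-nearest-neighbor regression on the embedded coordinates —
a Voronoi-style approximation of the decision space for display; it carries
no quantitative claims.

Behavior under the synthetic cohorts brackets the implementation: median
accuracy sits in [0.40, 0.60] at zero planted separation, reaches ≥ 0.95 at
5 pooled-SD separation, is monotone in between, and held-out animals drawn
from the control distribution are assigned to control in well over 75% of
cases.

## The synthetic-data module

The generators define the study conditions under which everything above is
validated; their defaults are fixed once:

* **Recordings** — 20 min at 1 kHz (synthesis needs no bandwidth above
  100 Hz; the MUA path is exercised separately at 32 kHz), 1/f¹ Gaussian
  background of 10 μV SD, 4 events/min with durations uniform in 1.5–4 s,
  each event a sum of one theta (5–11 Hz) and one beta-range (16–39 Hz)
  cosine with random phases under a tapered-cosine envelope, peak amplitude
  60 μV shared across channels up to a per-channel gain. The envelope's
  rise/fall ramp is a fixed 100 ms rather than a fraction of event
  duration: with duration-proportional ramps the signal near the nominal
  boundary is arbitrarily close to 0 μV and no detector could localize it,
  which would make boundary-accuracy validation meaningless rather than
  hard. Event count is deterministic at the nominal rate; onsets jitter
  around even spacing.
* **Spike trains** — inhomogeneous Poisson, rate elevated 10-fold during
  events, overall rate fixed at `10^log10_rate` (group defaults use the
  reported log₁₀ firing rates: control superficial −0.61, GE −2.1, deep
  −0.95 and −1.3). Phase locking is implemented by thinning candidate
  spikes against the carrier phase with acceptance proportional to a von
  Mises density and the candidate rate inflated by the exact mean
  acceptance `I₀(κ)e^{−κ}` — so the phase law is exactly von Mises *and*
  the marginal rate is exactly the target.
* **Ramp sessions** — per trial: ≥ 1.5 s baseline, 3-s linear ramp with a
  growing 20-Hz oscillation, baseline after. Tuned mode fires
  near-regularly at 60 ± 2 ms once the ramp passes 40% power; untuned mode
  is a renewal process with ISIs uniform over 10–500 ms — the natural
  "no preferred interval" null whose histogram is flat across the analysis
  range (a Poisson train would decay exponentially across it).
* **Feature cohorts** — unit-variance Gaussians per group; `effect_scale`
  is the per-feature mean separation in pooled-SD units (0 = identical
  distributions).
* **Behavior** — per-animal ratios `mean_dr + N(0, noise_sd)` clipped to
  (−1, 1), inverted into non-negative interaction times with a fixed total,
  so `noise_sd = 0` reproduces the requested ratio exactly.
* **Image stacks** — ellipsoidal somata (bright core, 0.3-intensity halo)
  on a jittered grid with non-overlapping 110×110 ROIs; spherical puncta
  (default rasterized volume ≈ 140 voxels) either embedded with a 2-voxel
  containment margin and ≥ 13-px mutual separation (so the maximum filter
  cannot merge them) or placed in the background away from all cells. Cell
  processes are *not* emulated (`branch_count` is 0): engulfment and shape
  validation need controlled geometry, and ramified processes would make
  planted containment ill-defined.

Every generator is bit-reproducible from its seed. What passing tests on
these fixtures do **not** show: robustness to non-stationary noise,
electrode drift, movement artifacts beyond the shared-component kind,
ambiguous event boundaries (real spindle bursts wax and wane), overlapping
cells, anisotropic point-spread blur, or staining variability. The
synthetic conditions are deliberately clean; they validate the algorithms'
correctness, not their field performance.

## Problem sizes and numerical choices

The shipped validation uses 20 simulated minutes for event detection, 30 s
of 32-kHz signal for MUA recall and 10 minutes for its noise floor, 500
spikes for coupling statistics, 2000 spikes per PPC calibration point,
cohorts of 60 animals with 100 CV iterations, 1000 null simulations with
1000 bootstrap resamples for test calibration, and single-cell image stacks
of 192×192×24 voxels — sizes chosen so the complete suite and the
acceptance script each run on a laptop-class single core in a few minutes
while leaving every statistical check well-powered. Degenerate inputs are
contracts, not crashes: constant groups yield flagged exact results,
empty spike trains a zero rate, a flat image zero cells, an empty event
list an explicit error for spectra (oscillatory power is undefined without
oscillations) and an occurrence of zero for summaries.

## Known limitations

* The event detector's Gaussian-fit threshold presumes silence-dominated
  recordings; on continuously active (older) cortex the histogram mode no
  longer isolates silence and `k` loses its calibration.
* Spike-triggered spectra are resolution-limited to 25 Hz by the 200-ms
  window; narrow-band effects inside beta cannot be localized more finely,
  and band summaries near the beta/gamma edge blur across it.
* The perimeter estimator is tuned for smooth outlines; strongly concave
  or one-pixel-wide structures (ramified processes) would need a different
  estimator.
* Pooled spike-triggered aggregation is the default; per-unit-then-pooled
  aggregation is available but group-level inference on nested designs
  should go through mixed models on the exported tables.
* The classifier's MI estimator discretizes features; with fewer than ~10
  animals per class the selection stage is effectively random (the kNN
  still works, tuned over the full feature set).
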