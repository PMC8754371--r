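---
title: "Analyzing intracerebral face-network responses: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing intracerebral face-network responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceflow)
```

## The scientific problem

Depth electrodes implanted in epilepsy patients for presurgical evaluation
offer millisecond-resolution field potentials from inside the
occipitotemporal cortex — the territory of the core face-processing network:
inferior occipital cortex (IOC), fusiform cortex (FC), inferior temporal
cortex (ITC), and superior temporal cortex (STC). Under a paradigm where a
neutral direct-gaze face (Face 1) changes expression and gaze direction
(Face 2), three questions can be addressed quantitatively:

1. **Which recording sites respond** to face onset and/or to the
   gaze/emotion change?
2. **When** does each region respond — does the N200 peak latency order the
   regions into a processing sequence?
3. **What** is each region sensitive to — gaze, emotion, or both — and how
   large are those effects?

A companion analysis asks which white-matter tracts could carry the implied
information flow, by overlapping responsive electrode locations with
population-level tract endpoint-density maps in MNI space.

Because raw patient recordings cannot be redistributed, the package pairs
every analysis stage with a synthetic-data generator that plants known
ground truth (component latencies and amplitudes, condition effects,
polarity reversals, artifacts, tract endpoints), so the entire pipeline is
testable end to end.

## Preprocessing model

The pipeline (in order): zero-phase filtering, long-epoch extraction,
artifact rejection, behavioral exclusions, 40 Hz low-pass and downsampling
to 400 Hz, bipolar derivation, and per-trial baseline z-scoring.

* **Filters.** High-pass 0.3 Hz (Butterworth order 4), band-stops 48–52 and
  58–66 Hz (order 4) against line noise, low-pass 40 Hz (order 6). All are
  applied forward–backward (`signal::filtfilt`), which squares the magnitude
  response and cancels phase distortion — chosen because phase shifts would
  bias the peak-latency analyses that are this pipeline's main output. The
  band-stop null at 50 Hz is so deep (design magnitude ~6e-8) that realized
  residuals are limited by double-precision arithmetic (~1e-5), not by the
  design.
* **Epochs.** One long epoch per trial, 400 ms before fixation to 1 s after
  target onset, half-open sample windows. Catch trials have no target; their
  epochs end at the latest possible target time (Face 2 + 450 ms) + 1 s so
  that all windows are comparable.
* **Rejection.** A ±750 µV threshold on any retained contact; marked
  epileptic/artifact and blink events reject a trial only when they fall
  between 500 ms before Face 1 and 300 ms after the target. Behavioral
  exclusions follow in a fixed order (pre-target presses, misses, false
  alarms, then a ±3 SD reaction-time trim computed on the surviving RTs);
  blocks retaining under half their trials are dropped whole. Each trial's
  first triggered reason is logged — rejection is monotone and auditable.
* **Downsampling.** 1024 Hz data are moved to the common 400 Hz grid by
  linear interpolation *after* the 40 Hz low-pass. With all energy below
  40 Hz, interpolation error is below 0.1%; a polyphase resampler was
  rejected because its passband ripple on test sinusoids exceeded 2%.
* **Bipolar derivation.** Adjacent same-shaft contacts are subtracted
  (deeper − shallower), cancelling reference and volume-conducted signal
  exactly and emphasizing local generators; a site's coordinate is the
  contact midpoint, and pairs spanning an excluded contact are not formed
  (they would have doubled inter-site distance). Polarity reversals across
  a site pair are the signature of a local source.
* **z-scoring.** Each trial and site is normalized by its own 100 ms
  pre-onset baseline, half-open `[-100, 0)` ms so the onset sample is never
  part of its own baseline. Baseline mean 0 and SD 1 hold exactly by
  construction; zero-variance baselines are flagged and dropped rather than
  silently producing infinities.

## Responsiveness: two-step testing

A site is *responsive* when (1) its trial-averaged z-scored waveform exceeds
|Z| = 1 (strictly — "exceeding" is read as >) anywhere in 0–400 ms, and (2)
a cluster-based sign-flip permutation t-test finds activity different from
zero. The cluster test forms temporally contiguous, same-sign runs of
samples whose pointwise |t| crosses the two-sided α = 0.05 threshold
(cluster mass = summed t, the conventional *maxsum* statistic), and builds
the null by flipping whole trials' signs (default 1000 draws, seeded). The
Monte Carlo p uses the +1-corrected estimator `(1 + #{null ≥ obs}) /
(1 + n_perm)`, so p can never be zero. For ≤ 12 trials the seeded Monte
Carlo p is verified in the tests against exhaustive 2^n enumeration.

Across sites, significance requires `p < 0.05/N` with N the number of
*screened-in* sites in the same ROI and hemisphere — sites failing the
liberal screen are declared unresponsive without ever running step 2 and do
not consume Bonferroni budget.

## ERP morphology, amplitude, and latency

**Slicing and rectification.** FC/ITC/STC sites are grouped into 10 mm
coronal slices (half-open bins A–E over y ∈ [−81, −31), F for anterior
sites); IOC is pooled. Because neighbouring bipolar sites flank local
generators with opposite signs, group averages are formed after polarity
rectification: find the absolute-average peak in a broad per-region window,
average each site's signed amplitude ±25 ms around it, and flip sites whose
mean is positive. The group mean is then invariant (exactly) to any site's
arbitrary polarity.

**Amplitude effect sizes.** Per site, the trialwise mean amplitude ±50 ms
around the group peak (no rectification) is summarized as one-sample
Cohen's d = µ/σ; |d| is reported against the 0.2/0.5/0.8 bands since the
bipolar sign is arbitrary.

**Jackknife latencies.** Single-site peak latencies are noisy, so latency
inference leaves out one site at a time, re-averages, and measures each
leave-one-out peak. The jackknife SD uses the standard inflation
`σ = sqrt((n−1)/n · Σ(θ_i − θ̄)²)` — leave-one-out values are (n−1)-fold
compressed, and for a linear statistic the inflated SD equals the analytic
SEM to machine precision (a test asserts this). Conditions are compared with
`t = (µ_A − µ_B)/σ_AB`, `σ_AB = sqrt(σ_A² + σ_B²)`, df = n_A + n_B − 2;
ROIs are compared pairwise (six tests, Bonferroni 0.05/6 applied at the
count of tests actually run) plus an omnibus one-way ANOVA on jackknife
values whose F is divided by (n−1)² (the mean per-group n when counts
differ), compensating the same compression.

**Peak refinement.** The peak is located by discrete argmax (ties to the
earliest latency) and then refined with a three-point parabolic fit,
yielding sub-sample latencies. The refinement matters: a grid-quantized
argmax is a non-smooth statistic whose jackknife variance estimate is
unstable — in simulation it produced degenerate zero-variance draws and
both under-coverage of confidence intervals and spurious pairwise
differences at the sampling step. `refine = "none"` restores the raw grid
latency for comparison.

## Gaze and emotion effects

On Face-2-responsive sites, a pointwise 2×2 between-trials ANOVA (emotion ×
gaze, leftward/rightward pooled as *averted*) runs at every sample in
0–400 ms with Type-II sums of squares (robust to the mild trial-count
imbalance the paradigm produces). Clusters of suprathreshold F values
(pointwise α = 0.05 on F(1, n−4)) are mass-summed and referred to
permutation nulls: main effects permute that factor's labels; the
interaction permutes the residuals of the additive model and adds them back
to the additive fit, preserving both main effects under the interaction
null. Effect sizes use the cluster with the largest |mass|: trialwise
time-averages in that window, two-sample Cohen's d with the pooled SD.
Within each ROI, gaze and emotion |d| values are compared by two-sample
t-tests across sites; across ROIs, one-way ANOVAs with post-hoc pairwise
t-tests (degenerate all-equal inputs return t = 0 / F = 0 rather than
erroring).

## Tract endpoints and overlap

Per subject and tract, streamlines are cleaned (removing those > 4 SD from
the tract centroid or mean length; zero-SD cases remove nothing), reoriented
against the first streamline so "first"/"last" nodes form coherent endpoint
collections, and binned into a 1 mm isotropic MNI grid (voxel = floor of the
mm coordinate; half-open voxels). Counts are smoothed with a *normalized
uniform spherical kernel* of 3 mm radius — "radius" is taken literally, not
as a FWHM — preserving the endpoint total exactly. Per-subject maps are
thresholded at 0.01 (strictly), binarized, and summed into subject-count
masks. The 0.01 threshold is applied by default to densities normalized by
the subject's endpoint total, which makes it invariant to streamline count;
the raw-count reading is available (`normalize = FALSE`). Overlap entries
are the proportion of a site group's MNI coordinates falling in voxels
supported by ≥ 100 subjects; tracts overlapping nothing are dropped from
the emitted matrix (and logged). Overlap is monotone non-increasing in the
validity threshold.

## The synthetic generator and its study conditions

ERP components are Gaussian envelopes — P100, N200 (negative by
convention), P250, and an STC slow wave — because only smooth single-peak
morphology is described for them; condition effects add amplitude/latency
deltas to the dominant negative component. Continuous recordings add
1/f background (exponent 1, the canonical LFP spectrum) plus a white floor,
per-contact polarity signs flipping across the planted generator, a spatial
amplitude falloff (Gaussian, 12 mm) so bipolar sites away from the reversal
still see signal, and injected artifacts (threshold excursions, spikes, and
blink templates on a designated scalp channel, mirroring blink detection on
the scalp electrode with the clearest blink signal).

Fixed study conditions used by the statistical validation (chosen once,
with rationale):

* *Group site ERPs* (`simulate_site_erps`): amplitude 3 z with 17% site
  scatter, site latency scatter 2 ms, residual noise 0.6 z **band-limited
  at an 8 ms correlation scale**. Band-limited noise is both more realistic
  (every waveform passed the 40 Hz low-pass) and statistically necessary:
  white noise makes the peak location non-smooth, and in simulation it
  inflated the null SD of the jackknife t from ~1.1 to ~2.5.
* *Latency ordering*: site counts 19/13/40/16 (IOC/ITC/FC/STC), matching
  the degrees of freedom reported for these regions; N200 at 150 ms in IOC
  versus 180 ms in ITC/FC; STC slow wave at 300 ms with 45 ms width (kept
  narrow enough to peak inside the 0–400 ms epoch). With these conditions
  the expected pairwise significance pattern (IOC before everything, ITC=FC,
  STC last) reproduces in ≈95% of runs at 0.05/6.
* *Effect-size recovery*: trial-gain SD 1.25 with 0.3 z sensor noise puts
  the analytic effect size of the ±50 ms window mean at d = 0.80; the
  generator reports this analytic value in its ground truth rather than
  back-fitting it from data.
* *Amplitude scale*: component amplitudes are in baseline-SD units and the
  paper of record gives no z-scale per component; defaults (N200 ≈ −3 z)
  are configuration, not published values.

## What passing tests do and do not show

The synthetic data are smooth, Gaussian, and stationary; real intracerebral
recordings have epileptiform transients, non-Gaussian noise, drifting
impedances, and morphology that varies within an ROI. Passing the planted
recovery suites demonstrates that the estimators are implemented correctly
and calibrated under the stated conditions — not that real-data effect sizes
or latencies will be estimated this well. Type-I control is verified under
exchangeable nulls (sign-symmetric trials; permutable labels); real trials
can violate exchangeability through slow drifts.

## Numerical choices and degenerate inputs

Half-open conventions everywhere (baselines, y-bins, voxels, epoch
windows); ties in peak search break to the earliest latency; x = 0 sites go
to the right hemisphere by convention (logged); zero-variance cases are
flagged (`d` undefined, degenerate baselines dropped, zero-SD outlier
criteria remove nothing, 0/0 t-statistics defined as 0); Monte Carlo p
values use the +1 correction; epoch boundary arithmetic guards decimal
times that are not exact binary floats with a 1e-6-sample epsilon.

Problem sizes in the validation suites — 1000 null simulations for each
type-I check with 199 permutations each, 400 replicates for recovery and
coverage, 100 runs for the ordering pattern, exhaustive enumeration at
n = 10 — were chosen so the whole suite completes in a few minutes on one
core while leaving Monte Carlo standard errors well inside the asserted
margins.

## Known limitations

* Latency localization assumes a single dominant deflection inside the
  search window; multimodal waveforms (e.g. mixed-polarity edge sites) can
  make the jackknife latencies jump between modes. Per-region search
  windows mitigate this.
* The jackknife CI for peak latencies is slightly anticonservative at
  n = 10 sites (simulated coverage ≈ 93% at nominal 95%), a known property
  of nonlinear leave-one-out statistics at small n.
* The blink detector is a robust-z threshold on a designated scalp channel,
  replacing interactive review; its parameters are configuration.
* The interaction permutation scheme (residual permutation under the
  additive model) is one of several defensible choices; the factorial
  cluster-forming threshold is configurable because no canonical value
  exists.
* Registration is out of scope: all coordinates (electrodes and
  streamlines) are assumed to already be in MNI millimetres.
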