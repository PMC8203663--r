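---
title: "Methods: HFB dynamics around food anticipation and consumption"
author: "foodcue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HFB dynamics around food anticipation and consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and procedures:
what each stage assumes, which constants matter, what the synthetic
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## The measurement model

Stereo-EEG depth electrodes record local field potentials at 1024 Hz from
contacts grouped along shafts. The quantity of interest is high-frequency
broadband (HFB) power, 70–170 Hz: the amplitude envelope of this band
tracks aggregate population spiking near the contact and is treated
throughout as the per-channel response variable. Two experimental designs
share one signal chain:

* **Task**: a 1 s visual cue (palatable vs. taste-neutral) is followed at
  3 s by delivery of the corresponding liquid over 3 s. Epochs are cut
  −2 to 6 s around cue onset; anticipation is 0–3 s, receipt 3–6 s.
* **Meal**: the time point just before food enters the mouth time-locks
  epochs of −5 to 5 s; bites are labelled entrée / non-entrée.

### Signal chain and its assumptions

1. **Notch filtering.** Mains contamination at 60/120/180 Hz is removed by
   cascaded 2nd-order Butterworth band-stops (two-pass, so 4th-order
   magnitude), width `f0/Q` with Q = 35. The notch design is a package
   choice; any zero-phase design with ≥30 dB attenuation at the line and
   <1 dB passband ripple is equivalent for these analyses. All zero-phase
   filtering adds 1 s of odd-reflection padding at the recording ends
   before the forward–backward pass, keeping IIR start-up transients out
   of retained samples.
2. **Laplacian re-referencing.** Each contact subtracts the mean of its
   two shaft neighbours (ends subtract their single neighbour; singleton
   shafts pass through with a warning). This suppresses volume-conducted
   far-field signal under the assumption that it is locally homogeneous
   along the shaft. Note the corollary used when building simulations: a
   response planted on one contact leaks, halved and sign-flipped, into
   its flanking contacts.
3. **Band power.** Butterworth band-pass of the band's stated order (HFB:
   8th; delta/theta/alpha/beta/gamma: 4th), magnitude of the FFT-based
   analytic signal, then a centred 200 ms boxcar. The envelope (not its
   square) is used. Because the Hilbert transform is computed on the full
   continuous recording before epoching, epoch edges carry no filter
   artifacts. The 200 ms boxcar means any rise in the envelope *leads*
   the underlying power rise by up to 100 ms — visible as a small
   negative bias in onset latencies (measured at −15 to −25 ms for
   planted responses).
4. **Epoching and z-scoring.** Epoch windows are half-open,
   `round(width × fs)` samples. Per channel, z-scores use the mean and SD
   of the *pooled* baseline samples across all trials (task: −0.6 to
   −0.1 s; meal: −5 to −4.5 s). Pooling is a deliberate choice: a
   per-trial SD over a 0.5 s window is an unstable divisor and would
   inflate trial-to-trial variance. A zero-variance baseline aborts with
   the channel named.
5. **Effect sizes.** Condition contrasts average z over the cue (0–1 s) or
   receipt (3–4 s) window per trial and report Cohen's *d* with the pooled
   SD, sign = palatable − neutral (entrée − non-entrée for meals).
   Channel-wise *d* values are tested across channels with a classical
   one-sample *t*.

## Cluster-based permutation tests

Pointwise two-sample *t* statistics are thresholded at the critical value
for cluster-forming α = 0.05; temporally contiguous supra-threshold runs
form clusters with mass Σ*t*; the null statistic is the maximum cluster
mass per permutation (maxsum), and each observed cluster gets
`p = (1 + #{null ≥ observed}) / (1 + n_perm)` with `n_perm = 1000` by
default. The +1 correction keeps p strictly positive.

* **Activity vs. baseline** (one-tailed, greater): because baseline and
  test windows have different time supports, the baseline comparator is
  each trial's time-averaged baseline value — a scalar per trial. The
  null swaps, per trial with probability ½, the trial's test segment with
  that scalar. This is one concrete reading of "shuffling data between
  the baseline and post-stimulus windows"; pooling all samples would be
  an alternative and is not implemented.
* **Condition vs. condition** (two-tailed): labels are shuffled; clusters
  are sign-separated so oppositely signed runs never merge. Null draws
  are made against a canonically (data-)ordered pooled trial set, which
  makes the null distribution a function of the pooled data only — with
  a fixed seed, swapping the two groups flips every cluster's sign and
  leaves every p unchanged.
* Group minimums are 3 trials per condition — enough for the *t* to be
  defined; the small-sample regime is exercised by an enumeration test
  (below).

Calibration is checked empirically: over 200 white-noise simulations both
engines produce an any-cluster false-positive rate between 1% and 10% at
nominal α = 0.05 (measured: ~2% and ~6%). The smoothed-envelope regime is
additionally covered by full null sessions through the whole chain, where
the per-channel false-"responsive" rate measured ~6%.

## Layered site classification

Per channel and phase (anticipation windows start at 0 s, receipt at 3 s):

1. **Responsive.** Five consecutive, non-overlapping 500 ms windows tile
   the first 2.5 s of the phase. In each window and each condition
   separately, the vs-baseline cluster test runs; the channel is
   responsive if any significant cluster spans ≥ 200 ms. Five
   non-overlapping 500 ms windows cannot tile a 3 s phase, so the tiling
   covers 0–2.5 s (receipt: 3–5.5 s) — the final half second of each
   phase is untested, a documented consequence of the window arithmetic.
2. **Specific.** Only windows that contained a significant step-1 response
   are tested palatable vs. neutral, at threshold
   `0.05 / (number of windows tested)` — the Bonferroni denominator is
   the number of windows actually carried into step 2, not always 5.
   The channel is specific if significant between-condition spans
   intersect the step-1 responsive spans (union over conditions) by
   ≥ 100 ms in total.
3. **Effect size.** For specific channels, Cohen's *d* of per-trial mean z
   over the union of specific spans. Category precedence:
   specific > responsive > inactive.

Meal channels are classified by a single between-conditions cluster test
over −1 to 1 s around food intake, with an inclusion criterion of at
least 10 bites per food type.

Topology questions use Pearson chi-square without continuity correction
on region × category tables (empty regions dropped with a warning,
empty categories dropped as uninformative); the task ↔ meal association
is a 2 × 2 chi-square over a common channel set, with degenerate margins
reported as undefined rather than forced.

## Response onset latency

Single-trial, on the z-scored envelope: the first run of ≥ 100 ms above
z = 2 starts the search; a 200 ms window from that sample is sliced into
100 ms segments at 10 ms steps (11 segments — the 90% overlap reading of
the segmentation; the count is logged rather than hidden); each segment
gets an OLS line; among the five largest (signed) slopes the segment with
the smallest mean squared residual is the onset segment, and its first
time point is the latency. Signed slopes are used because onsets are
rises; an absolute-slope variant would also track offsets and is not
implemented. Trials with no qualifying run are recorded as absent and
excluded (not imputed). Thresholding at z = 2 on pooled-baseline z-scores
makes "2 SDs of baseline" exact by construction.

Region summaries pool latencies over channels, trials and both
conditions; the 95% CI of the median is a 1000-resample percentile
bootstrap (the CI method is unstated in the source procedure; the
bootstrap is labelled in the output).

## Single-trial decoding

One observation per (channel, trial): mean HFB z in 0–0.5, 0.5–1, 1–2 and
2–3 s. Stratified 5-fold cross-validation; per fold the features are
standardised with training-fold statistics, PCA (training-fold fit) keeps
the minimal component count reaching 95% variance, and a weighted KNN
votes with squared-inverse-distance weights over k = 10 Euclidean
neighbours. Standardising before PCA is a choice — on raw window means the
first component would simply track overall scale. The positive-class vote
share (Σ weights of positive neighbours / Σ weights) is the ROC score; a
zero distance saturates the vote, which is correct behaviour for a
duplicate observation. Feature importance retrains the full pipeline 100
times per feature with that feature's values freely permuted across
observations (class-balanced swapping would be an alternative reading);
`p = (1 + #{shuffled TPR ≥ observed}) / (1 + 100)`.

## Spike detection and interpolation

Meal recordings are cleaned before band-power extraction. Detection:
band-pass 20–50 Hz per channel, average across channels, flag
`|x| > 5 × MAD-scaled SD`, merge flags within 100 ms, spike time = peak.
The robust scale estimate matters: with an ordinary SD, twenty large
spikes inflate their own threshold enough to mask the smallest of them.
Interpolation replaces ±50 ms around each spike, per channel, with
surrogate noise whose amplitude spectrum is the average over
spike-free 100 ms chunks of the flanking second, with uniform random
phases (Hermitian-symmetrised) and 10 ms linear crossfades; samples
outside the windows are bit-identical. "Within 2× of background" for the
20–50 Hz power of a single replaced 100 ms window is a noisy estimate —
the mean ratio across windows sits near 1.1 with individual windows
fluctuating by ±0.5 — so aggregate summaries are reported alongside the
per-window maximum.

## The synthetic generator

`generate_background()` shapes white noise to a 1/f^β spectrum (β = 1 by
default, typical of LFP), scales to 20 µV RMS, and adds a 60 Hz line with
half/quarter-amplitude harmonics. `inject_responses()` adds 70–170 Hz
band-limited noise under a trapezoidal envelope (linear 100 ms rise and
fall, total duration 1 s by default) with plateau gain × (channel
background SD), locked to events of a given condition and phase — an
amplitude-modulated noise carrier rather than a sinusoid, so Hilbert
envelopes behave like real high gamma. `inject_spikes()` plants
all-channel biphasic transients (derivative-of-Gaussian sharp phase,
spectral peak near 20 Hz, plus a slower opposite wave) at Poisson times
with a 0.5 s minimum separation, keeping transients non-overlapping.
Sessions default to 40 trials per condition (80 total, the low end of the
task design; configurable), 9.5 s trial spacing so −2..6 s epochs never
overlap, and 10.5 s bite spacing for meals.

What the generator does *not* emulate: cognitive trial-to-trial gain
variability (planted responses vary only through the noise carrier, so
synthetic effect sizes at the planted gains are an order of magnitude
larger than empirical ones — passing recovery tests demonstrates
correctness of the machinery, not realistic sensitivity), chewing/EMG
artifact, electrode drift, cross-channel correlated background, or
behaviourally jittered response onsets. Ground-truth categories follow
directly from the planted gains (all zero → inactive; equal positive →
responsive; unequal → specific), and demo scenarios group equal-category
channels per shaft so Laplacian leakage cannot contaminate an unplanted
flank.

## Numerical choices and degenerate inputs

* Epoch windows half-open; sample 1 is t = 0; onsets are seconds from
  recording start.
* Filter orders are effective band-pass orders (the design order passed
  to `signal::butter` is half of it); two-pass filtering squares the
  magnitude response.
* FFTs are padded to lengths with small prime factors before the
  analytic-signal step.
* Zero pooled-baseline variance, a condition with fewer than 2 trials,
  fewer than 3 channels in the group test, mismatched channel sets, and
  degenerate contingency margins all abort with named errors rather than
  propagate NaN.
* Permutation seeds derive child seeds per channel/window (kept below
  2^31), so channel results are independent of evaluation order.
* KNN distance ties break by observation index; zero distances are
  floored at 1e−12 before inversion.

## Validation problem sizes

The test-suite and `scripts/acceptance.R` size their simulations for a
single CPU: 200 null simulations at 200 permutations for type-I
calibration; one 12-channel, 40-trial session for category recovery
(expected ≥ 9/12 correct; measured 9–11 across seeds); eight 4-channel,
30-trial sessions for onset-latency rank recovery (planted 630 / 830 /
900 / 930 ms; rank recovered in 8/8, |median bias| ≤ ~22 ms); decoder
checks on 200-observation Gaussian feature sets; and a 20-spike, 2-minute
cleaning loop. The full suite runs in about 2.5 minutes.

## Known limitations

* EDF support is 16-bit with a single data record — sufficient for
  round-tripping and clinical exports, not a general EDF+ implementation.
* No spatial (cross-channel) clustering, TFCE, or frequency-dimension
  clustering; no correction across channels (the design corrects across
  time windows only).
* Latency differences between regions are summarised, not tested.
* The meal analysis assumes bite annotations are given; video processing
  is out of scope.
* Region labels are metadata; no atlas computation is performed.
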