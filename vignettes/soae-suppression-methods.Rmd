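---
title: "Measuring contralateral suppression of spontaneous otoacoustic emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contralateral suppression of spontaneous otoacoustic emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A healthy cochlea emits narrowband sounds — spontaneous otoacoustic
emissions (SOAEs) — that a miniature microphone sealed in the ear canal can
record without any stimulus. Because SOAEs are a by-product of outer-hair-cell
amplification, and because the medial olivocochlear (MOC) efferent system
turns that amplification down when the opposite ear hears sound, the dip in
SOAE level during contralateral stimulation indexes top-down efferent
control of the inner ear.

`soaesupp` implements the full measurement chain for a trial-based version
of this paradigm: speech syllables (~500 ms) are presented to one ear while
SOAEs are recorded in the other; each trial begins with a silent 1,500-ms
lead-in, so every trial provides its own pre-stimulus baseline. The package
covers

1. spectral analysis and SOAE identification in quiet baseline recordings,
2. exclusion filters for unstable and mains-contaminated peaks and the
   test-ear rule,
3. per-trial suppression measurement by narrowband peak tracking,
4. the statistical stage: factor-loading composite scores and the linear
   models relating per-trial suppression to cognitive composites and
   language-group membership, and
5. a synthetic-cohort generator with known ground truth, so that every one
   of those stages can be validated by parameter recovery rather than by
   eyeballing.

## Spectral analysis

All spectra come from a short-time Fourier transform with a 22,050-point
transform length, a 16,384-point Hamming window, and a 4,096-point hop at a
44.1 kHz sampling rate. The bin spacing is therefore exactly
`44100 / 22050 = 2` Hz, and a 500-ms measurement window contains five or
six frame centers (hop = 92.9 ms). Frame timestamps use the window-center
convention so that spectral smearing is symmetric around events. Magnitudes
are normalised by `2 / sum(window)`, which makes an on-bin sinusoid of
amplitude *a* read `20*log10(a) + calibration_db`; normalised magnitudes
are clipped at 1e-10 before the logarithm so silence maps to a finite
floor.

"dB SPL" in this package always means *level under a calibration constant*:
the dB SPL of a full-scale sinusoid. Real hardware determines this constant
with a probe-fit sweep; the synthetic world simply fixes it (default 30 dB)
and records it in each dataset's ground-truth sidecar. Any consistent
constant is acceptable because every downstream quantity is a difference of
levels under the same constant.

The baseline spectrum is the power-domain average of all frames of a ~3-min
quiet recording, converted to dB afterwards. Power-domain averaging is
unbiased for stationary signals; dB-domain averaging is reserved for the
per-trial "average of the peaks", where the measured quantity is itself
defined as an average of dB values. Whether the original analysis averaged
frames or used one long transform is not specified anywhere; frame
averaging was chosen because it also yields the per-frame spectra the
tracking stage needs.

## SOAE identification and exclusion

No universally agreed detection criterion for SOAEs exists, so detection is
deliberately conventional and configurable: a candidate is a local spectral
maximum at least 6 dB above a running-median noise floor (~200 Hz
bandwidth), searched between 500 Hz and 12 kHz; when two candidates fall
within 10 Hz of each other only the higher is kept.

Two exclusion filters follow, with deliberate boundary conventions:

* **Stability.** Each candidate's level is measured in the first four
  non-overlapping 30-s segments of the baseline; a sample SD (n−1) above
  6 dB excludes the peak. The threshold is *exclusive*: SD exactly 6 dB is
  kept. Which four 30-s periods of a 3-min baseline to use is not
  determined by the rule itself; the first four are used.
* **Line noise.** Peaks within 5 Hz (*inclusive*) of an integer multiple of
  60 Hz are excluded as potential mains artifacts.

Both filters only set flags — frequencies and levels are never modified —
and exclusion labels are recomputed from independent per-filter flags, so
the two filters commute.

The task phase is recorded from the **test ear**: the ear with more
surviving emissions between 1,000 and 10,000 Hz. Ties go to the right ear
(a fixed, documented convention; the tally ignores excluded and
out-of-range peaks). Subjects with no surviving emission in either ear are
excluded from analysis and logged.

## Per-trial suppression

For each surviving emission and each trial, the tracked peak — the highest
local maximum within ±25 Hz (inclusive) of the baseline emission frequency
— is extracted from every frame whose center lies in the 500-ms window
starting at speech onset, and in the 500-ms window ending at *trial* onset
(the image/video onset, not speech onset; the 1,500-ms lead-in separates
the two). The trial's suppression is the difference of the two dB-domain
frame averages; more negative values mean more suppression. Windows are
half-open with a frame-center inclusion rule and no partial-frame
weighting. Frames without a trackable local maximum are dropped; a window
with fewer than three usable frames marks the whole (trial × emission) row
missing, with a machine-readable reason, rather than being silently
dropped.

### The window-smearing bias

The 16,384-point Hamming window spans ±186 ms around each frame center, so
frames counted inside the 500-ms stimulus window inevitably average in
un-suppressed signal from just outside it. For a step-like suppression of
magnitude *m* this attenuates the recovered mean delta to roughly
0.86–0.88 · *m* (the exact value follows from Hamming-weighting the gain
envelope; the test suite computes it analytically and checks the pipeline
against it to 0.1 dB). This is a property of the stated analysis
parameters, not of the implementation: any analysis using a 371-ms window
on a 500-ms stimulus smears this way, and measured suppression magnitudes
should be interpreted accordingly. At 2 dB of injected suppression the
attenuation (~0.3 dB) exceeds the ±0.2 dB band the recovery check uses at
smaller magnitudes, and the package reports it rather than compensating
for it: an empirical deconvolution would presume the very dynamics under
study.

## The statistical stage

Cognitive composites are weighted sums of z-standardized task scores
(sample SD, n−1) using fixed factor loadings: Control = 0.922·flanker +
0.525·pattern + 0.509·card-sort; Working Memory = 0.999·working-memory +
0.223·vocabulary − 0.119·card-sort − 0.128·pattern. All non-blank loadings
are used by default because the compositing rule is stated over the task
scores and their loadings without restriction; a `"salient"` variant
(drop |loading| < 0.3) is available since reporting conventions often
describe factors by their salient loadings only.

Three models are fit to trial-level observations with ordinary least
squares, mirroring the original analysis structure:

* **Cognitive:** `delta ~ Control * WorkingMemory`;
* **Group:** `delta ~ bilingual + baseline_level`, where the baseline
  covariate is the subject-level per-emission baseline level (the emission's
  level in the baseline phase, or the across-trial mean of pre-trial
  windows when no peak table is supplied), with the test ear available as a
  robustness covariate and an acquisition-age variant within bilinguals;
* **Residualized:** the cognitive model's residuals regressed on group,
  which assesses the group effect left after the composites have explained
  what they can.

Trial-level OLS ignores the within-subject correlation of trials, as the
original analysis did; the package therefore also computes cluster-robust
covariance (clustered on subject; the bias-reduced HC3-type estimator with
a t reference on subjects−1 degrees of freedom, which stays close to
nominal coverage and test size down to about a dozen clusters, where the
plain CR1 estimator under-covers and over-rejects) for every fit. The
classical OLS
output is the default shown; the cluster-robust version is what the
package's own calibration checks rely on, because only it has approximately
correct coverage when suppression varies at the subject level. p values are
two-sided from the t distribution and no multiple-testing correction is
applied (none is part of the original procedure).

`correlation_t()` converts a correlation to its t statistic,
`t = r·sqrt(n−2)/sqrt(1−r²)` on n−2 df — with r = −0.196 and n = 32 it
returns t = −1.09 on 30 df, the worked example used as an exact check of
the statistical conventions.

## The synthetic cohort

The generator emulates the study design: 32 subjects by default (11
monolingual, 11 early bilingual, 10 late bilingual), 240 trials in 10
blocks, speech onset exactly 1,500 ms after trial onset, ~500-ms syllables,
3-min two-ear baselines. Emissions are amplitude-stabilised sinusoids with
slow Ornstein–Uhlenbeck frequency and level wander (defaults 1 Hz and
0.3 dB SD — far inside the 25 Hz tracking window) rather than full
limit-cycle oscillators; this exercises detection and tracking without
modelling cochlear mechanics. Per ear, subjects draw 0–4 emissions (mean
~1.7, so the better ear averages ~2 — matching the ~2.1 tested peaks per
subject typical of SOAE cohorts), uniformly over 1.1–6.4 kHz with levels
around −4.9 dB SPL (monolinguals) or −2.9 dB SPL (bilinguals). A white
noise floor sits at −25 dB SPL per bin (~20 dB below typical peaks) and
mains interference is injected at 60/120/180 Hz plus an in-band harmonic at
1,080 Hz, which the line-noise filter must catch. Emission frequencies are
sampled at least 10 Hz away from mains multiples and 80 Hz from in-band
harmonics so that "every injected emission outside exclusion zones is
detectable" is a well-defined claim.

Suppression follows first-order efferent dynamics: a 10-ms onset latency
and a 25-ms time constant toward the subject's asymptotic magnitude during
each speech sound, with symmetric recovery — the fast (tens of
milliseconds) component of the contralateral MOC effect. Trials repeat
every 5 s (1.5 s lead-in + 0.5 s speech + 3 s silence), long enough for
complete recovery before the next pre-trial baseline window; the original
report does not state its inter-trial interval, so 3 s is a package
default, not an inferred value.

Each subject's suppression magnitude comes from a generative model on the
trial-delta (dB) scale:

```
expected_delta = -mu + b_control*C + b_wm*W + b_interaction*C*W
                 + b_group*bilingual (+ b_aoa*AoA among bilinguals)
magnitude      = max(0, -(expected_delta + eps)),  eps ~ N(0, residual_sd)
```

so negative `b_control` yields a negative fitted Control coefficient, as in
the analysis being emulated. Defaults: mu = 1 dB (typical for contralateral
MOC effects; the emulated study reports no delta magnitudes, so this is a
free simulator parameter), `b_control = -0.3`, `b_wm = +0.3`,
`b_interaction = -0.1`, `b_group = -0.8` dB, `residual_sd = 0.25` dB,
trial-level noise 0.5 dB. The signs mirror the reported effects; the
magnitudes are set by a design-stage power analysis so that, at the default
cohort size, all three signs are recoverable in ≥95% of replicates —
effects much smaller than the sampling error of a 32-subject design would
make parameter-recovery validation vacuous. `b_aoa` defaults to 0 (and the
default task scores carry no group shifts) so that each coefficient's
marginal meaning matches its name; `group_task_shift = 1` switches on
group differences in the simulated task scores (bilinguals higher on
control-loaded tasks, monolinguals higher on the English working-memory
and vocabulary tasks) for experiments on mediated group effects.

Two generation paths exist deliberately. The **audio path** renders full
ear-canal recordings and exercises the entire spectral chain; the
**measurement path** (`simulate_trial_measurements()`) draws trial deltas
directly from the generative model. Statistical calibration (sign recovery,
CI coverage, permutation size) uses the measurement path at the full
default design size — 50 replicates of 32 subjects × 240 trials are a few
minutes of computation there, while the audio path validates separately
that the spectral pipeline recovers injected suppression. Spectral
validation uses jitter-free cohorts of 12 subjects, and suppression
recovery uses 3 subjects × 40 trials per magnitude with 2-s baselines
(truth peaks are used directly there; detection completeness has its own
12-subject check with full 180-s baselines).

## What the synthetic world does and does not show

The generator reproduces the *statistical* structure the analysis assumes:
narrowband emissions over a stationary noise floor, mains lines, step-like
trial-locked suppression, covariate-dependent magnitudes, subject-level
heterogeneity. It does not model middle-ear muscle reflexes, ear-canal
pressure drift, probe slippage, emission interactions or frequency pulling,
breathing/swallowing artifacts, or slow (tens of seconds) efferent
components. Passing parameter-recovery tests therefore demonstrates that
the pipeline measures what it claims to measure under the stated
assumptions — not that those assumptions exhaust real recordings.

## Numerical conventions and edge cases

* Spectrum levels are floored at −200 dB re full scale before any log.
* Strictly monotonic spectra inside a tracking window yield a *missing*
  tracked peak, never an endpoint extremum.
* The stability SD uses the n−1 denominator; four equal segment levels give
  SD 0.
* Measurement windows lying wholly outside the recording raise an error;
  windows inside the recording with too few usable frames yield flagged
  missing rows.
* All randomness flows from explicit integer seeds; identical
  configurations produce byte-identical datasets (and identical manifest
  checksums).
* Datasets round-trip through plain formats: WAV (float32 by default),
  tab-separated tables, and a JSON ground-truth sidecar sufficient to
  recompute every injected quantity.

## Known limitations

* The ±0.2 dB suppression-recovery band is not attainable at 2 dB injected
  magnitude under the stated analysis window (see the window-smearing
  section); the package reports the attenuated value honestly.
* Cluster-robust inference with ~12 clusters is itself only approximate;
  the calibration checks run at the default 32-subject design where the
  approximation is adequate.
* Factor loadings are consumed as constants; estimating them (factor
  analysis with oblique rotation) is out of scope.
* The command-line wrapper is a thin convenience over the R functions; the
  functions and this vignette are the primary interface.
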