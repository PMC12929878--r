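---
title: "Adaptive listening-test procedures: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive listening-test procedures: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auditest)
```

## What this package models

Remote listening tests for hearing-device users replace a calibrated
laboratory chain with the participant's own streaming setup. The engine
in this package reproduces the computational core of such a system
offline: level calibration in dB FS, signal-to-noise mixing, adaptive
staircase tracking with its threshold estimators, paired-comparison and
ranking task structures, the technical checks that guard data quality,
and a simulated-listener harness that validates every procedure without
human participants.

All audio lives in a single representation: a mono sample vector on a
±1.0 full-scale convention plus a sampling rate (`waveform()`). 0 dB FS
is the RMS of a constant full-scale signal; a full-scale sine sits at
−3.01 dB FS. Test material is calibrated to a common −25 dB FS RMS
(`level_spec()` default), which leaves generous headroom while keeping
presentation loudness consistent once the listener has set a comfortable
level in the loudness check.

## The adaptive staircases

Both threshold procedures are transformed up–down staircases
(`staircase_config()`): after `n_up` consecutive correct responses the
task is made harder by one step, after an incorrect response it is made
easier; a flip of the movement direction logs a reversal.

* **Digits-in-noise (DIN).** Triplets of digits in speech-shaped noise,
  tracked on SNR: 1-up-1-down, 2 dB steps, start 0 dB, limits ±20 dB,
  24 trials. A trial is correct only when all three digits are reported
  in order (`score_din_trial()`). The speech-reception threshold (SRT)
  is the mean presented SNR of the final 16 trials after discarding the
  first 8 (`estimate_srt_final_trials()`). 1-up-1-down converges at the
  50%-correct point of the psychometric function.
* **STRIPES.** Discrimination of an upward-sweeping target among
  downward-sweeping standards, tracked on sweep *density*: 2-up-1-down,
  start 1.1, steps of 0.5 for the first four reversals and 0.2 for the
  final four, stopping at eight reversals. The run threshold is the mean
  density of the final four reversals
  (`estimate_threshold_reversal_mean()`); the task is run twice and the
  run thresholds averaged (`combine_runs()`). 2-up-1-down converges at
  the 70.7%-correct point.

Three semantics are deliberately pinned down because they are genuinely
open choices in any staircase implementation:

* **Reversals at the rails.** Levels are clamped to the track limits. A
  clamped move still updates the *intended* direction, and a reversal is
  logged exactly when the intended direction flips. This keeps reversal
  counting well defined when a good listener pins the track at a rail.
* **Step-schedule timing.** The step size of a move is the one
  associated with the number of reversals already logged at the moment
  of the move, including a reversal logged by the current response. The
  move away from the fourth reversal therefore already uses the fine
  step.
* **Counter resets.** The consecutive-correct counter resets after every
  level change and after any incorrect response — the standard
  transformed up–down convention.

The engine is verified bit-exactly against an independent brute-force
trace simulator over thousands of random response sequences, and the
closed-form traces hold: an all-correct responder yields an SRT of
−19.625 dB, an all-incorrect responder +19.625 dB, and a strictly
alternating responder −1.0 dB.

## Stimulus synthesis

The engine must be testable fully offline, so the stimulus generators
are synthetic surrogates with controlled, assertable properties rather
than recordings:

* **Digit tokens** (`synth_digit_token()`) are harmonic complexes with a
  digit-specific fundamental (105–249 Hz), two digit-specific spectral
  resonances and a digit-specific modulation rate. They are not
  intelligible speech; they are ten mutually distinct tokens (all 45
  pairwise normalized cross-correlations stay below 0.9) calibrated to
  −25 dB FS.
* **Speech-shaped noise** (`synth_speech_shaped_noise()`) shapes seeded
  Gaussian noise in the frequency domain so its smoothed spectrum
  matches a reference's long-term average spectrum (default smoothing
  bandwidth 100 Hz), then calibrates to the reference RMS. Stationarity
  holds to well under ±3 dB per 250 ms window.
* **STRIPES-style stimuli** (`synth_stripes()`) sum `n_components`
  exponential sweeps whose instantaneous log-frequency position advances
  `density` times per stimulus and wraps, components staggered evenly.
  Up and down differ only in sweep sign; a spectrogram-ridge slope
  statistic separates them perfectly at the easiest density of 1.1. The
  geometry is a documented surrogate that carries the adaptive
  procedure; it makes no claim of perceptual equivalence to published
  ripple stimuli, and the density unit is the sweep-traversal count per
  stimulus, not a perceptually validated scale.

Noise mixing (`mix_at_snr()`) holds the speech level fixed and scales
the noise, consistent with material calibrated to a fixed presentation
level; the realized component SNR equals the request to floating-point
precision (≪ 1e−9 dB). Noise longer than the speech is cropped from a
seeded random offset; shorter noise is rejected rather than looped to
avoid splice artifacts. Calibration that would push a peak past full
scale raises an error naming the required gain reduction instead of
silently limiting. Durations convert to sample counts by rounding half
up, and a 200 ms leading silence (`prepend_silence()`) guards stimulus
onsets against streaming wake-up truncation.

## Technical checks

The **connection check** (`connection_check()`) decides whether the
stimulus leaked through the device loudspeakers instead of streaming
directly to the hearing device. It compares playback and recording by
(a) the peak of the normalized temporal cross-correlation over lags up
to 200 ms and (b) the Pearson correlation of the smoothed amplitude
spectra after best-lag alignment — computed on matched-length segments
so a pure delay does not depress the spectral metric. A high value of
*either* metric indicates a match, i.e. a leak, and the check fails;
both metrics are reported regardless of verdict, are confined to
[−1, 1], and are invariant to the recording's overall level and
polarity. A digitally silent recording is *inconclusive*, never a pass.

The default thresholds (0.25 for the cross-correlation peak, 0.5 for the
spectral correlation, 9-bin spectral smoothing) were calibrated once on
the seeded synthetic scene grid produced by `simulate_leak_scene()`
(delayed, attenuated, low-pass-filtered playback plus stationary room
noise): leak-free scenes produce false alarms at 0/100 seeds, detection
is monotone in leak level, and leaks 10 dB above the noise floor are
detected at 100/100. Field behavior with real rooms, reverberation and
nonstationary noise will be less clean — the published experience with
such checks is that high ambient noise provokes false alarms, which is
tolerable because the check is advisory, not blocking.

The **loudness check** records one comfort gain per session and locks
it; gains that would clip the probe are rejected. The **microphone
check** gates on recorded energy against a −60 dB FS silence floor,
truncates at the configured duration cap, and carries the 500 ms arm
delay in its result for the session runner.

## Task structures and sessions

Ordered tasks step through a manifest in fixed, seeded-random
(a permutation — each stimulus exactly once per run) or adaptive order,
where the staircase level selects the manifest row of equal difficulty.
Paired tasks enumerate the cross product of two stimulus sets by
default — the natural design for comparing two processing conditions
item by item; an all-pairs-within-one-set mode is available behind
`within_set = TRUE` since the alternative reading is also plausible.
Ranked tasks insert each stimulus into the ranked-so-far list by binary
search against the interval midpoint (even intervals round toward the
better-ranked end, deterministically), which attains the
⌈log₂ k⌉-comparison bound per insertion; with any transitive comparator
the result equals the descending latent order — verified exhaustively
for all 720 permutations at n = 6 — and an inconsistent judgment still
yields *a* total order without error, though its content then depends on
the transcript. The session state machine accumulates idle time, warns
after 60 s without a response, terminates after 180 s (both
configurable), preserves recorded trials on warning and termination, and
counts runs toward completion.

## Scoring and persistence

Keyword (sentence) trials score 0–3 by exact token match after
lower-casing and punctuation stripping; 15 trials aggregate to
100·Σ/45 percent. Because manual scoring criteria for morphological
variants are never fully specified, leniency (plural/tense suffixes) is
off by default and available as a flag — a documented choice, not a
reproduction of any particular scorer. Digit trials are all-or-nothing
and order-sensitive. Vocal responses enter as token transcripts; no
speech recognition is attempted.

Manifests are UTF-8 CSV with a mandatory header
(`filename, difficulty_level, response_options, correct_answer,
condition`); validation is total, reporting every problem with its row
number. Result exports are a per-trial CSV plus a JSON settings blob
carrying an explicit schema version and trial count; import verifies
both and the round trip is the identity on the record set. Participant
tokens are 128-bit random hex strings scoped to a project and carry no
personal data. Stimulus bundles are gzip-compressed tar archives built
with R's internal tar, unpacking byte-identical.

## The simulated listener and what validation shows

`psychometric_listener()` is a cumulative-Gaussian observer:
P(correct) = γ + (1 − γ − λ)·Φ(±(level − μ)/σ), with the sign set by
whether higher levels are easier (SNR tracks) or harder (density
tracks). The DIN listener responds at the triplet level — one Bernoulli
per trial — because the scoring rule is all-or-nothing and triplet-level
psychometrics is the standard abstraction for digit tests. For STRIPES
the guess rate is fixed at 1/2, since the target is always the first or
last of three intervals.

Validation targets come from classical transformed up–down theory, not
from any particular participant group: across 500 seeded runs, the mean
DIN SRT lands within ±1.0 dB of the listener's 50% point (observed bias
≈ 0.01 dB for μ = −8 dB, σ = 2 dB), and the mean combined STRIPES
threshold within ±0.3 density of the 70.7% point (observed bias ≈ −0.15
for a listener whose 70.7% point is 4.0, σ = 0.8). The residual STRIPES
bias is the expected signature of a short eight-reversal track that
starts well below threshold, with the coarse-to-fine step change and a
hard floor at density 1.0; it sits well inside the tolerance the
procedure itself claims. Keyword simulations recover the per-condition
keyword probabilities to binomial error and preserve their ordering.

These simulations validate the *procedures*, not human performance: the
psychometric parameters are illustrative, the synthetic stimuli are
surrogates, and no claim is made of reproducing any published group
mean.

## Problem sizes and numerical choices

The validation suite uses problem sizes chosen to make the statistical
assertions sharp while staying comfortably interactive: 1 000 random
response sequences per staircase config for oracle equivalence, 500
seeded runs/sessions for convergence, 100-seed scene grids for the
connection check, 1 000 random waveform pairs for mixing exactness, and
exhaustive permutation checks up to n = 6 for ranking. Synthesis tests
run at 16 kHz with half- to one-second stimuli; nothing in the engine
depends on these sizes. Tolerances are stated where the quantity is
analytic (1e−9 dB for calibration and SNR) and statistical elsewhere
(binomial error bands, the staircase convergence bands above).

## Known limitations

* No acoustic calibration to absolute sound pressure levels; all levels
  are dB FS, so absolute detection thresholds are out of reach.
* Digit and sweep stimuli are synthetic surrogates; perceptual validity
  of stimulus content is explicitly not claimed.
* The connection check's operating point is calibrated on a synthetic
  scene family; real acoustic environments are noisier in structure.
* Vocal responses are scored from transcripts; no recognition engine is
  included.
* Interleaved multi-condition adaptive tracking uses independent tracks
  per condition; no shared-track variant is provided.
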