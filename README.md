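# auditest

Offline, scriptable engine for remote listening tests of the kind used
with cochlear-implant recipients and other hearing-device users. Web
systems for remote audiometry stream calibrated stimuli to the
participant's own device; everything perceptual in such a system —
levels, adaptive procedures, checks, scoring — is computation that can
be implemented, simulated and verified without a browser or a
participant. That computational core is what this package provides, for
researchers who want to prototype, validate or re-analyze such tests in
R.

## What it implements

* **Audio core** — a mono `waveform` type on a ±1.0 full-scale
  convention; RMS levels in dB FS with exact calibration
  (`calibrate_rms()`, default target −25 dB FS); SNR mixing that holds
  the speech level fixed and scales the noise so the realized component
  ratio is exact (`mix_at_snr()`); onset-guard silence
  (`prepend_silence()`, 200 ms default); mono WAV I/O (PCM16/24,
  float32). Synthetic generators for digit-like tokens, speech-shaped
  stationary noise matched to a reference spectrum, and STRIPES-style
  concurrent swept sinusoids with a controllable sweep density.
* **Staircases** — a generic transformed up–down engine
  (`staircase_config()`, `staircase_update()`) with the two concrete
  procedures: digits-in-noise (1-up-1-down, 2 dB steps, 24 trials, SRT =
  mean SNR of the final 16 trials after discarding 8) and STRIPES
  (2-up-1-down on density, start 1.1, steps 0.5 then 0.2 after four of
  eight reversals, threshold = mean of the final four reversal
  densities, two runs averaged). 1-up-1-down converges at the
  50%-correct point, 2-up-1-down at 70.7%.
* **Tasks** — ordered (fixed / seeded-random / adaptive) stimulus
  selection from CSV manifests, paired comparisons over the cross
  product of two sets, ranking by binary insertion at the
  ⌈log₂ k⌉-comparison bound, and a session state machine with
  inactivity warning and termination.
* **Checks** — the connection check, which detects loudspeaker leakage
  by the peak normalized temporal cross-correlation and the correlation
  of smoothed amplitude spectra (a match in either domain means the
  audio did not stream directly, so the check fails); a synthetic
  leak-scene generator for testing it; loudness (comfort gain, locked
  per session) and microphone (energy floor, duration cap) checks.
* **Scoring & I/O** — three-keyword sentence scoring (0–3 per trial,
  percent of 45 keywords per 15-trial list), all-or-nothing ordered
  digit-triplet scoring, per-condition summaries, validated stimulus
  manifests with row-addressed errors, versioned lossless result
  export/import, anonymous 128-bit participant tokens.
* **Simulation** — cumulative-Gaussian listeners
  (`psychometric_listener()`) and harnesses that run the full procedures
  end to end (`run_din_simulation()`, `run_stripes_simulation()`,
  `run_keyword_simulation()`), reporting bias against the procedure's
  theoretical convergence point.

Results objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a listener with a speech-reception threshold of −8 dB SNR
(slope 2 dB) running the 24-trial digits-in-noise procedure 500 times:

```r
library(auditest)

listener <- psychometric_listener(threshold_mu = -8, slope_sigma = 2)
report <- run_din_simulation(listener, n_runs = 500, seed = 1)
glance(report)
#> # A tibble: 1 × 7
#>   procedure n_runs  mean    sd target     bias  seed
#>   <chr>      <dbl> <dbl> <dbl>  <dbl>    <dbl> <dbl>
#> 1 din          500 -8.01 0.717     -8 -0.01000     1
```

The mean estimated SRT over 500 runs is −8.01 dB: the 1-up-1-down track
recovers the listener's 50%-correct SNR with a bias of −0.01 dB and a
run-to-run SD of 0.72 dB. A single track is a tibble away:

```r
st <- staircase_run(din_staircase_config(),
                    function(level) respond(listener, level))
glance(st)
#> # A tibble: 1 × 4
#>   n_trials n_reversals current_level finished
#>      <int>       <int>         <dbl> <lgl>
#> 1       24          13            -8 TRUE
autoplot(st)   # level per trial, reversals circled
```

The connection check on a simulated leak scene (playback delayed 30 ms,
attenuated, low-pass filtered at 2 kHz, with room noise):

```r
t <- (0:7999) / 16000
pb <- calibrate_rms(
  waveform(sin(2 * pi * (300 * t + 2700 * t^2)), 16000), level_spec(-25))
rec <- simulate_leak_scene(pb, leak_gain_db = -20, delay_ms = 30,
                           lowpass_hz = 2000, noise_level_dbfs = -50,
                           seed = 2)
connection_check(pb, rec)
#> <connection check: FAIL>
#>   xcorr_peak: 0.7441
#>   spectral_corr: 0.8161
#>   best_lag_ms: 30.25
#>   advisory: Recording matches playback: stimulus likely played over
#>   loudspeakers, not a direct audio connection.
```

The recording matches the playback (cross-correlation peak 0.74 at the
injected 30 ms lag), so the check fails — the stimulus leaked through
the loudspeakers. With no leak (`leak_gain_db = -Inf`) both metrics
drop near zero and the check passes.

A thin command-line front end over the same functions is included at
`inst/cli/auditest.R` (connection-check, validate-manifest, make-token,
simulate subcommands).

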