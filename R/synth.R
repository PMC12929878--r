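#' Synthetic spoken-digit surrogate token
#'
#' Generates a short harmonic-complex token with a digit-specific
#' fundamental, two digit-specific spectral resonances and a
#' digit-specific amplitude-modulation rate, so each of the ten tokens has
#' a distinct spectro-temporal signature. These tokens stand in for a
#' recorded digit corpus so the digits-in-noise machinery can be exercised
#' fully offline; they are not intended to be intelligible speech.
#'
#' @param digit Integer 0-9.
#' @param sample_rate Sampling rate in Hz.
#' @param duration_s Token duration in seconds.
#' @param level_dbfs Calibration target in dB FS.
#' @param seed Integer seed (controls harmonic starting phases).
#' @return A calibrated [waveform()].
#' @export
synth_digit_token <- function(digit, sample_rate = 44100, duration_s = 0.35,
                              level_dbfs = -25, seed = 1L) {
  if (!is.numeric(digit) || length(digit) != 1L || digit != round(digit) ||
      digit < 0 || digit > 9) {
    abort("`digit` must be a single integer in 0-9.",
          class = "auditest_bad_argument")
  }
  digit <- as.integer(digit)
  n <- round_half_up(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- 105 + 16 * digit
  # two "formant"-like resonances sliding in opposite directions with digit
  res1 <- 320 + 70 * digit
  res2 <- 2600 - 140 * digit
  harmonics <- seq(f0, 3600, by = f0)
  phases <- withr::with_seed(seed, runif(length(harmonics), 0, 2 * pi))
  amp <- exp(-((log(harmonics) - log(res1))^2) / (2 * 0.45^2)) +
    0.7 * exp(-((log(harmonics) - log(res2))^2) / (2 * 0.35^2))
  x <- numeric(n)
  for (k in seq_along(harmonics)) {
    x <- x + amp[k] * sin(2 * pi * harmonics[k] * t + phases[k])
  }
  am_rate <- 3 + 1.5 * digit
  x <- x * (1 + 0.35 * sin(2 * pi * am_rate * t))
  x <- x * cos_ramp(n, round_half_up(0.025 * sample_rate))
  calibrate_rms(waveform(x, sample_rate), level_spec(level_dbfs))
}

# raised-cosine onset/offset envelope
cos_ramp <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0 && 2 * n_ramp <= n) {
    r <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / (n_ramp - 1)))
    env[seq_len(n_ramp)] <- r
    env[(n - n_ramp + 1):n] <- rev(r)
  }
  env
}

#' Speech-shaped stationary noise
#'
#' Shapes seeded Gaussian noise so its smoothed power spectrum matches the
#' long-term average spectrum of a reference waveform, and calibrates the
#' result to the reference's RMS level. The output is stationary: the RMS
#' of any short window stays within a few dB of the global RMS.
#'
#' @param reference A nonzero [waveform()] providing the target spectrum
#'   (typically the concatenated speech material).
#' @param duration_s Output duration in seconds, > 0.
#' @param seed Integer seed; the same seed reproduces the samples exactly.
#' @param smoothing_hz Spectral smoothing bandwidth in Hz used when
#'   extracting the reference's long-term envelope.
#' @return A [waveform()] at the reference's sample rate and RMS level.
#' @export
synth_speech_shaped_noise <- function(reference, duration_s, seed = 1L,
                                      smoothing_hz = 100) {
  check_waveform(reference, "reference")
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    abort("`duration_s` must be a single positive number.",
          class = "auditest_bad_argument")
  }
  rate <- reference$sample_rate
  ref_rms <- rms_dbfs(reference) # errors on all-zero reference
  # long-term amplitude envelope of the reference, smoothed
  nr <- length(reference$samples)
  mag <- Mod(fft(reference$samples))[seq_len(nr %/% 2 + 1)]
  k <- max(3L, round_half_up(smoothing_hz * nr / rate))
  env <- running_mean(mag, k)
  f_ref <- (seq_along(env) - 1) * rate / nr
  n <- round_half_up(duration_s * rate)
  w <- withr::with_seed(seed, rnorm(n))
  # symmetric real filter magnitude on the noise's frequency grid
  f_out <- pmin(0:(n - 1), n - (0:(n - 1))) * rate / n
  h <- approx(f_ref, env, xout = f_out, rule = 2)$y
  y <- Re(fft(fft(w) * h, inverse = TRUE)) / n
  calibrate_rms(waveform(y, rate), level_spec(ref_rms))
}

running_mean <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # pad the ends where the window runs off the vector
  half <- (k - 1L) %/% 2L
  n <- length(x)
  if (n > 2 * half) {
    sm[seq_len(half)] <- sm[half + 1L]
    sm[(n - half + 1L):n] <- sm[n - half]
  } else {
    sm[] <- mean(x)
  }
  sm
}

#' Specification of a STRIPES-style swept-sinusoid stimulus
#'
#' The stimulus is a sum of concurrent exponential (log-frequency) sweeps.
#' The `density` parameter controls how many sweep traversals of the
#' f_low-f_high range occur per stimulus duration: higher density packs the
#' spectro-temporal "stripes" closer together and makes the up/down
#' discrimination harder. Upward and downward variants differ only in the
#' sweep sign.
#'
#' @param density Sweep density, dimensionless, >= 1.
#' @param direction `"up"` or `"down"`.
#' @param duration_s Stimulus duration in seconds, > 0.
#' @param f_low_hz,f_high_hz Sweep frequency range, 0 < f_low < f_high.
#' @param n_components Number of concurrent sweeps, staggered evenly.
#' @return A `stripes_spec` object.
#' @export
stripes_spec <- function(density, direction = c("up", "down"),
                         duration_s = 1, f_low_hz = 250, f_high_hz = 8000,
                         n_components = 4L) {
  direction <- match.arg(direction)
  if (!is.numeric(density) || length(density) != 1L || density < 1) {
    abort("`density` must be a single number >= 1.",
          class = "auditest_bad_argument")
  }
  if (duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "auditest_bad_argument")
  }
  if (!(0 < f_low_hz && f_low_hz < f_high_hz)) {
    abort("Require 0 < f_low_hz < f_high_hz.", class = "auditest_bad_argument")
  }
  if (n_components < 1) {
    abort("`n_components` must be >= 1.", class = "auditest_bad_argument")
  }
  structure(
    list(density = density, direction = direction, duration_s = duration_s,
         f_low_hz = f_low_hz, f_high_hz = f_high_hz,
         n_components = as.integer(n_components)),
    class = "stripes_spec"
  )
}

#' Synthesize a STRIPES-style stimulus
#'
#' Each component's instantaneous frequency traverses the log-frequency
#' range `density` times over the stimulus, wrapping around; components are
#' staggered evenly in log frequency so several sweeps are concurrent at
#' every instant. The geometry is a documented surrogate sufficient to
#' carry the up/down discrimination and its adaptive procedure; it makes
#' no claim of perceptual equivalence to the published ripple stimuli.
#'
#' @param spec A [stripes_spec()].
#' @param sample_rate Sampling rate in Hz; `f_high_hz` must be below
#'   Nyquist.
#' @param level_dbfs Calibration target in dB FS.
#' @param seed Integer seed (component starting phases).
#' @return A calibrated [waveform()].
#' @export
synth_stripes <- function(spec, sample_rate = 44100, level_dbfs = -25,
                          seed = 1L) {
  stopifnot(inherits(spec, "stripes_spec"))
  if (spec$f_high_hz >= sample_rate / 2) {
    abort("`f_high_hz` must be below Nyquist.",
          class = "auditest_bad_argument")
  }
  n <- round_half_up(spec$duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  log_ratio <- log(spec$f_high_hz / spec$f_low_hz)
  phases <- withr::with_seed(seed, runif(spec$n_components, 0, 2 * pi))
  x <- numeric(n)
  for (k in seq_len(spec$n_components)) {
    pos <- (spec$density * t / spec$duration_s +
              (k - 1) / spec$n_components) %% 1
    if (spec$direction == "down") pos <- 1 - pos
    f_inst <- spec$f_low_hz * exp(log_ratio * pos)
    phase <- 2 * pi * cumsum(f_inst) / sample_rate
    x <- x + sin(phase + phases[k])
  }
  x <- x * cos_ramp(n, round_half_up(0.01 * sample_rate))
  calibrate_rms(waveform(x, sample_rate), level_spec(level_dbfs))
}

#' Specification of one digits-in-noise trial
#'
#' @param digits Ordered triple of digits, each 0-9.
#' @param snr_db Signal-to-noise ratio in dB, within -20..20.
#' @param speech_level_dbfs RMS calibration level of the digit material.
#' @return A `din_trial_spec` object.
#' @export
din_trial_spec <- function(digits, snr_db, speech_level_dbfs = -25) {
  digits <- as.integer(digits)
  if (length(digits) != 3L || anyNA(digits) ||
      any(digits < 0L | digits > 9L)) {
    abort("`digits` must be exactly three integers in 0-9.",
          class = "auditest_bad_argument")
  }
  if (!is.numeric(snr_db) || length(snr_db) != 1L ||
      snr_db < -20 || snr_db > 20) {
    abort("`snr_db` must be a single number in [-20, 20].",
          class = "auditest_bad_argument")
  }
  structure(
    list(digits = digits, snr_db = snr_db,
         speech_level_dbfs = speech_level_dbfs),
    class = "din_trial_spec"
  )
}

#' Assemble a digits-in-noise trial stimulus
#'
#' Concatenates three synthetic digit tokens with short gaps, calibrates
#' the triplet, and mixes it with speech-shaped stationary noise matched
#' to the triplet's long-term spectrum at the requested SNR.
#'
#' @param spec A [din_trial_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @param gap_s Inter-digit gap in seconds.
#' @param seed Integer seed for noise synthesis and crop offset.
#' @return The mixed trial [waveform()].
#' @export
synth_din_trial <- function(spec, sample_rate = 44100, gap_s = 0.1,
                            seed = 1L) {
  stopifnot(inherits(spec, "din_trial_spec"))
  gap <- numeric(round_half_up(gap_s * sample_rate))
  toks <- lapply(spec$digits, function(d) {
    synth_digit_token(d, sample_rate,
                      level_dbfs = spec$speech_level_dbfs, seed = seed)$samples
  })
  speech <- calibrate_rms(
    waveform(c(toks[[1]], gap, toks[[2]], gap, toks[[3]]), sample_rate),
    level_spec(spec$speech_level_dbfs)
  )
  noise <- synth_speech_shaped_noise(speech, duration_s(speech) + 0.5,
                                     seed = seed)
  mix_at_snr(speech, noise, spec$snr_db, seed = seed)
}
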