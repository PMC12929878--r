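#' Connection-check configuration
#'
#' The connection check decides whether a played stimulus leaked through
#' the device loudspeakers (and was picked up by the microphone) instead
#' of reaching the hearing device over a direct audio connection. Two
#' similarity metrics are computed between playback and recording: the
#' peak of the normalized temporal cross-correlation within a lag window,
#' and the Pearson correlation of the smoothed amplitude spectra after
#' best-lag alignment. A high value of either indicates a match, i.e. a
#' leak, and the check FAILS; sufficiently different signals pass.
#'
#' Default thresholds are calibrated on the seeded synthetic leak-scene
#' grid (see [simulate_leak_scene()]) to give high leak detection at
#' leak-to-noise ratios of 10 dB and above with a low false-alarm rate on
#' leak-free scenes.
#'
#' @param xcorr_threshold Peak |normalized cross-correlation| at or above
#'   which a temporal match is declared, in (0, 1].
#' @param spectral_corr_threshold Amplitude-spectrum correlation at or
#'   above which a spectral match is declared, in (0, 1].
#' @param max_lag_ms Maximum lag searched (acoustic + buffering delay).
#' @param spectrum_smoothing_bins Running-mean width (bins) applied to the
#'   amplitude spectra before correlating.
#' @return A `connection_check_config` object.
#' @export
connection_check_config <- function(xcorr_threshold = 0.25,
                                    spectral_corr_threshold = 0.5,
                                    max_lag_ms = 200,
                                    spectrum_smoothing_bins = 9L) {
  if (!(xcorr_threshold > 0 && xcorr_threshold <= 1) ||
      !(spectral_corr_threshold > 0 && spectral_corr_threshold <= 1)) {
    abort("Thresholds must lie in (0, 1].", class = "auditest_bad_config")
  }
  if (max_lag_ms <= 0) {
    abort("`max_lag_ms` must be positive.", class = "auditest_bad_config")
  }
  structure(
    list(xcorr_threshold = xcorr_threshold,
         spectral_corr_threshold = spectral_corr_threshold,
         max_lag_ms = max_lag_ms,
         spectrum_smoothing_bins = as.integer(spectrum_smoothing_bins)),
    class = "connection_check_config"
  )
}

new_check_result <- function(check, passed, metrics, advisory = "") {
  structure(
    list(check = check, passed = passed, metrics = metrics,
         advisory = advisory),
    class = "check_result"
  )
}

#' @export
print.check_result <- function(x, ...) {
  verdict <- if (is.na(x$passed)) "inconclusive" else {
    if (x$passed) "PASS" else "FAIL"
  }
  cat(sprintf("<%s check: %s>\n", x$check, verdict))
  for (m in names(x$metrics)) {
    cat(sprintf("  %s: %.4g\n", m, x$metrics[[m]]))
  }
  if (nzchar(x$advisory)) cat("  advisory:", x$advisory, "\n")
  invisible(x)
}

#' @export
tidy.check_result <- function(x, ...) {
  tibble(check = x$check, metric = names(x$metrics),
         value = unlist(x$metrics, use.names = FALSE))
}

#' @export
glance.check_result <- function(x, ...) {
  tibble(check = x$check, passed = x$passed, advisory = x$advisory)
}

# normalized cross-correlation of x against sliding windows of y,
# nonnegative lags 0..max_lag; FFT-based numerator, cumsum-based norms
ncc_lags <- function(x, y, max_lag) {
  nx <- length(x)
  ny <- length(y)
  max_lag <- min(max_lag, ny - nx)
  nfft <- stats::nextn(nx + ny, 2)
  X <- fft(c(x, numeric(nfft - nx)))
  Y <- fft(c(y, numeric(nfft - ny)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / nfft
  num <- cc[seq_len(max_lag + 1L)]
  y2 <- c(0, cumsum(y^2))
  seg_norm <- sqrt(y2[(0:max_lag) + nx + 1L] - y2[(0:max_lag) + 1L])
  r <- num / (sqrt(sum(x^2)) * seg_norm)
  r[!is.finite(r)] <- 0
  r
}

smoothed_amp_spectrum <- function(x, bins) {
  mag <- Mod(fft(x))[seq_len(length(x) %/% 2 + 1L)]
  running_mean(mag, bins)
}

#' Run the connection check
#'
#' @param playback The stimulus [waveform()] that was played.
#' @param recording The concurrent microphone recording, same sample rate
#'   and at least as long as the playback.
#' @param cfg A [connection_check_config()].
#' @return A `check_result`. `passed = TRUE` means no match was found
#'   (direct connection plausible); `passed = FALSE` means the recording
#'   matches the playback in time or spectrum (loudspeaker leak);
#'   `passed = NA` marks an inconclusive check (e.g. silent microphone).
#'   Metrics `xcorr_peak`, `spectral_corr` and `best_lag_ms` are always
#'   reported. Both metrics are invariant to the recording's overall
#'   level and polarity.
#' @export
connection_check <- function(playback, recording,
                             cfg = connection_check_config()) {
  check_waveform(playback, "playback")
  check_waveform(recording, "recording")
  stopifnot(inherits(cfg, "connection_check_config"))
  if (playback$sample_rate != recording$sample_rate) {
    abort("Playback and recording must share a sample rate.",
          class = "auditest_rate_mismatch")
  }
  if (length(recording) < length(playback)) {
    abort("Recording must be at least as long as the playback.",
          class = "auditest_bad_argument")
  }
  if (all(recording$samples == 0)) {
    return(new_check_result(
      "connection", NA,
      list(xcorr_peak = NA_real_, spectral_corr = NA_real_,
           best_lag_ms = NA_real_),
      "Recording is digital silence; microphone may be muted. Inconclusive."
    ))
  }
  rate <- playback$sample_rate
  max_lag <- round_half_up(cfg$max_lag_ms * rate / 1000)
  r <- ncc_lags(playback$samples, recording$samples, max_lag)
  best <- which.max(abs(r))
  xcorr_peak <- abs(r[best])
  lag <- best - 1L
  seg <- recording$samples[(lag + 1L):(lag + length(playback))]
  sx <- smoothed_amp_spectrum(playback$samples, cfg$spectrum_smoothing_bins)
  sy <- smoothed_amp_spectrum(seg, cfg$spectrum_smoothing_bins)
  spectral_corr <- if (sd(sx) == 0 || sd(sy) == 0) 0 else cor(sx, sy)
  match_found <- xcorr_peak >= cfg$xcorr_threshold ||
    spectral_corr >= cfg$spectral_corr_threshold
  advisory <- if (match_found) {
    "Recording matches playback: stimulus likely played over loudspeakers, not a direct audio connection."
  } else {
    "No match between recording and playback; direct audio connection plausible."
  }
  new_check_result(
    "connection", !match_found,
    list(xcorr_peak = xcorr_peak, spectral_corr = spectral_corr,
         best_lag_ms = lag * 1000 / rate),
    advisory
  )
}

#' Simulate the acoustic scene recorded during a connection check
#'
#' Produces a synthetic microphone recording: the playback delayed,
#' attenuated and low-pass filtered (the loudspeaker-to-microphone leak
#' path) plus stationary Gaussian room noise. With `leak_gain_db = -Inf`
#' only noise is returned - the direct-audio scenario in which nothing
#' reaches the loudspeakers.
#'
#' @param playback The stimulus [waveform()].
#' @param leak_gain_db Leak path gain in dB (`-Inf` for no leak).
#' @param delay_ms Acoustic + buffering delay in ms, >= 0.
#' @param lowpass_hz Optional low-pass cutoff of the leak path (Hz).
#' @param noise_level_dbfs RMS level of the room noise in dB FS, or
#'   `-Inf` for a noiseless scene.
#' @param tail_ms Extra recording length beyond delay + playback.
#' @param seed Integer seed; the scene is fully reproducible.
#' @return The simulated recording [waveform()].
#' @export
simulate_leak_scene <- function(playback, leak_gain_db = -20, delay_ms = 30,
                                lowpass_hz = NULL, noise_level_dbfs = -40,
                                tail_ms = 50, seed = 1L) {
  check_waveform(playback, "playback")
  if (delay_ms < 0) {
    abort("`delay_ms` must be >= 0.", class = "auditest_bad_argument")
  }
  rate <- playback$sample_rate
  d <- round_half_up(delay_ms * rate / 1000)
  n <- d + length(playback) + round_half_up(tail_ms * rate / 1000)
  leak <- numeric(n)
  if (is.finite(leak_gain_db)) {
    sig <- playback$samples
    if (!is.null(lowpass_hz)) {
      bf <- signal::butter(4, lowpass_hz / (rate / 2), type = "low")
      sig <- as.numeric(signal::filter(bf, sig))
    }
    sig <- sig * 10^(leak_gain_db / 20)
    leak[(d + 1L):(d + length(sig))] <- sig
  }
  noise <- numeric(n)
  if (is.finite(noise_level_dbfs)) {
    noise <- withr::with_seed(seed, rnorm(n))
    noise <- noise / sqrt(mean(noise^2)) * 10^(noise_level_dbfs / 20)
  }
  out <- leak + noise
  if (all(out == 0)) out[1] <- .Machine$double.eps # degenerate: keep nonzero
  waveform(out, rate)
}

#' Loudness (comfort level) check
#'
#' The listener sets a comfortable presentation gain while a probe
#' stimulus, calibrated like the test material, plays. The chosen gain is
#' recorded once per session and locked: the listener is asked not to
#' change the level afterwards, so a second attempt is rejected. Gains
#' that would push the probe past full scale are rejected with an
#' advisory.
#'
#' @param probe The probe [waveform()] (calibrated to the project level).
#' @param chosen_gain_db Gain chosen by the listener, in dB.
#' @param session Optional `task_session`; when given, the gain is stored
#'   on it and a second call errors.
#' @return A `check_result`; when `session` is supplied, the updated
#'   session is attached as attribute `"session"`.
#' @export
loudness_check <- function(probe, chosen_gain_db, session = NULL) {
  check_waveform(probe, "probe")
  peak <- max(abs(probe$samples)) * 10^(chosen_gain_db / 20)
  if (peak > 1) {
    return(new_check_result(
      "loudness", FALSE,
      list(chosen_gain_db = chosen_gain_db, resulting_peak = peak),
      sprintf("Gain of %+.1f dB would clip the probe (peak %.3f); reduce by at least %.1f dB.",
              chosen_gain_db, peak, 20 * log10(peak))
    ))
  }
  if (!is.null(session)) {
    stopifnot(inherits(session, "task_session"))
    if (!is.null(session$comfort_gain_db)) {
      abort("Comfort gain already set for this session; presentation level is locked.",
            class = "auditest_gain_locked")
    }
    session$comfort_gain_db <- chosen_gain_db
  }
  res <- new_check_result(
    "loudness", TRUE,
    list(chosen_gain_db = chosen_gain_db, resulting_peak = peak),
    "Comfort level recorded; please do not change the device volume."
  )
  if (!is.null(session)) attr(res, "session") <- session
  res
}

#' Microphone check
#'
#' Verifies that a vocal-response recording contains signal above a
#' silence floor. The recording button's arm delay (default 500 ms) is
#' applied by the session runner before capture starts and is reported in
#' the result for session metadata; recordings longer than the configured
#' cap are truncated.
#'
#' @param recorded The captured [waveform()].
#' @param arm_delay_ms Visual arm delay before capture, in ms.
#' @param max_duration_s Maximum recording duration; longer input is
#'   truncated at the cap.
#' @param silence_floor_dbfs RMS level below which the recording counts
#'   as silent.
#' @return A `check_result` with metrics `rms_dbfs`, `duration_s`,
#'   `truncated` and `arm_delay_ms`.
#' @export
microphone_check <- function(recorded, arm_delay_ms = 500,
                             max_duration_s = 10,
                             silence_floor_dbfs = -60) {
  check_waveform(recorded, "recorded")
  truncated <- FALSE
  cap <- round_half_up(max_duration_s * recorded$sample_rate)
  if (length(recorded) > cap) {
    recorded <- waveform(recorded$samples[seq_len(cap)],
                         recorded$sample_rate)
    truncated <- TRUE
  }
  lvl <- if (all(recorded$samples == 0)) -Inf else rms_dbfs(recorded)
  passed <- lvl > silence_floor_dbfs
  new_check_result(
    "microphone", passed,
    list(rms_dbfs = lvl, duration_s = duration_s(recorded),
         truncated = truncated, arm_delay_ms = arm_delay_ms),
    if (passed) "Recording level OK." else
      "Recording is silent or below the floor; please retry closer to the microphone."
  )
}
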