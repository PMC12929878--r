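#' RMS level of a waveform in dB FS
#'
#' Levels are expressed relative to digital full scale: a constant signal at
#' amplitude 1.0 has an RMS level of 0 dB FS, and a full-scale sine of
#' about -3.01 dB FS.
#'
#' @param w A [waveform()] with at least one nonzero sample.
#' @return RMS level in dB FS (a single number).
#' @examples
#' rms_dbfs(waveform(rep(1, 100), 16000)) # 0 dB FS
#' @export
rms_dbfs <- function(w) {
  check_waveform(w)
  ms <- mean(w$samples^2)
  if (ms == 0) {
    abort("RMS level of an all-zero signal is undefined.",
          class = "auditest_undefined_level")
  }
  10 * log10(ms)
}

#' Target presentation level
#'
#' Stimuli in a project are calibrated to a common RMS level in dB FS
#' (default -25 dB FS) so presentation loudness is consistent once the
#' listener has set a comfortable level.
#'
#' @param target_rms_dbfs Target RMS level in dB FS; must be negative
#'   (0 dB FS and above cannot be reached without clipping for any
#'   non-constant signal).
#' @return A `level_spec` object.
#' @export
level_spec <- function(target_rms_dbfs = -25) {
  if (!is.numeric(target_rms_dbfs) || length(target_rms_dbfs) != 1L ||
      !is.finite(target_rms_dbfs) || target_rms_dbfs >= 0) {
    abort("`target_rms_dbfs` must be a single finite negative number.",
          class = "auditest_bad_level_spec")
  }
  structure(list(target_rms_dbfs = target_rms_dbfs), class = "level_spec")
}

#' Calibrate a waveform to a target RMS level
#'
#' Applies a single positive gain so the output RMS level equals the target
#' exactly (to well under 1e-9 dB). If the required gain would push the peak
#' above full scale the function refuses rather than limiting, and the error
#' names the gain reduction needed.
#'
#' @param w A nonzero [waveform()].
#' @param spec A [level_spec()], or a single negative number taken as the
#'   target in dB FS.
#' @return A calibrated [waveform()].
#' @examples
#' w <- waveform(sin(2 * pi * 100 * (0:1599) / 16000), 16000)
#' rms_dbfs(calibrate_rms(w, level_spec(-25)))
#' @export
calibrate_rms <- function(w, spec = level_spec()) {
  check_waveform(w)
  if (is.numeric(spec)) spec <- level_spec(spec)
  stopifnot(inherits(spec, "level_spec"))
  gain <- 10^((spec$target_rms_dbfs - rms_dbfs(w)) / 20)
  out <- w$samples * gain
  peak <- max(abs(out))
  if (peak > 1) {
    abort(
      sprintf(
        paste0("Calibration to %.2f dB FS would clip (peak %.4f > 1.0); ",
               "reduce the target by at least %.2f dB."),
        spec$target_rms_dbfs, peak, 20 * log10(peak)
      ),
      class = "auditest_headroom_error"
    )
  }
  waveform(out, w$sample_rate)
}

#' Mix speech and noise at a requested SNR
#'
#' The speech (target) level is held fixed and the noise is scaled so the
#' realized RMS ratio of the two mixed components equals the requested
#' signal-to-noise ratio. Noise longer than the speech is cropped from a
#' seeded random offset; shorter noise is rejected.
#'
#' @param speech Target [waveform()].
#' @param noise Masker [waveform()], same sample rate, at least as long.
#' @param snr_db Requested SNR in dB (speech re. noise).
#' @param seed Integer seed controlling the crop offset when the noise is
#'   longer than the speech.
#' @return The mixture as a [waveform()], with attributes `noise_gain`
#'   (linear gain applied to the noise) and `noise_offset` (0-based crop
#'   offset in samples).
#' @export
mix_at_snr <- function(speech, noise, snr_db, seed = 1L) {
  check_waveform(speech, "speech")
  check_waveform(noise, "noise")
  if (speech$sample_rate != noise$sample_rate) {
    abort("`speech` and `noise` must share a sample rate.",
          class = "auditest_rate_mismatch")
  }
  if (!is.numeric(snr_db) || length(snr_db) != 1L || !is.finite(snr_db)) {
    abort("`snr_db` must be a single finite number.",
          class = "auditest_bad_argument")
  }
  ns <- length(speech$samples)
  nn <- length(noise$samples)
  if (nn < ns) {
    abort("Noise must be at least as long as the speech.",
          class = "auditest_bad_argument")
  }
  offset <- 0L
  if (nn > ns) {
    offset <- withr::with_seed(seed, sample.int(nn - ns + 1L, 1L)) - 1L
  }
  seg <- noise$samples[(offset + 1L):(offset + ns)]
  s_rms <- sqrt(mean(speech$samples^2))
  n_rms <- sqrt(mean(seg^2))
  if (s_rms == 0 || n_rms == 0) {
    abort("SNR is undefined when speech or noise has zero RMS.",
          class = "auditest_undefined_level")
  }
  g <- (s_rms / n_rms) * 10^(-snr_db / 20)
  out <- waveform(speech$samples + g * seg, speech$sample_rate)
  attr(out, "noise_gain") <- g
  attr(out, "noise_offset") <- offset
  out
}

#' Prepend digital silence to a waveform
#'
#' Streaming transports (e.g. Bluetooth to a hearing device) can wake up
#' late and cut off stimulus onsets; a short leading silence (default in
#' this system is 200 ms) guards against that. The original samples are
#' preserved bit-exactly after the pad.
#'
#' @param w A [waveform()].
#' @param duration_ms Silence duration in milliseconds, >= 0. Rounded
#'   half-up to an integer sample count.
#' @return The padded [waveform()].
#' @examples
#' length(prepend_silence(waveform(rnorm(100), 44100), 200)) # 100 + 8820
#' @export
prepend_silence <- function(w, duration_ms = 200) {
  check_waveform(w)
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L ||
      !is.finite(duration_ms) || duration_ms < 0) {
    abort("`duration_ms` must be a single nonnegative number.",
          class = "auditest_bad_argument")
  }
  n <- round_half_up(duration_ms * w$sample_rate / 1000)
  if (n == 0) return(w)
  waveform(c(numeric(n), w$samples), w$sample_rate)
}
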