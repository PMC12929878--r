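test_that("rms_dbfs matches closed forms and rejects silence", {
  expect_equal(rms_dbfs(waveform(rep(1, 100), 16000)), 0)
  expect_equal(rms_dbfs(waveform(rep(0.5, 100), 16000)), 20 * log10(0.5))
  # full-scale sine over an integer number of cycles: A / sqrt(2)
  t <- (0:15999) / 16000
  expect_equal(rms_dbfs(waveform(sin(2 * pi * 100 * t), 16000)),
               20 * log10(1 / sqrt(2)), tolerance = 1e-10)
  expect_error(rms_dbfs(waveform(numeric(10), 16000)),
               class = "auditest_undefined_level")
})

test_that("calibrate_rms is exact, idempotent, and shape-preserving", {
  t <- (0:15999) / 16000
  sine <- waveform(sin(2 * pi * 100 * t), 16000)
  cal <- calibrate_rms(sine, level_spec(-25))
  expect_equal(rms_dbfs(cal), -25, tolerance = 1e-12)
  # derived gain: 10^((-25 - (-3.0103)) / 20) ~ 0.07944
  expect_equal(max(abs(cal$samples)), 10^((-25 - 20 * log10(1 / sqrt(2))) / 20),
               tolerance = 1e-6)
  # idempotence: calibrating twice changes nothing
  expect_equal(calibrate_rms(cal, level_spec(-25))$samples, cal$samples)
  # tiny constant signal scales up by 10^((-25 + 60)/20) ~ 56.234
  tiny <- calibrate_rms(waveform(rep(0.001, 50), 8000), level_spec(-25))
  expect_equal(tiny$samples[1] / 0.001, 10^(35 / 20), tolerance = 1e-9)
  # shape preserved up to one positive factor
  set.seed(11)
  w <- waveform(rnorm(300) * 0.01, 8000)
  calw <- calibrate_rms(w, level_spec(-30))
  expect_equal(cor(calw$samples, w$samples), 1, tolerance = 1e-12)
  expect_error(calibrate_rms(waveform(numeric(5), 8000)),
               class = "auditest_undefined_level")
})

test_that("calibration that would clip raises a headroom error", {
  # a spiky signal whose peak/RMS ratio forces clipping at -1 dB FS
  x <- c(rep(0.001, 1000), 1)
  expect_error(calibrate_rms(waveform(x, 8000), level_spec(-1)),
               class = "auditest_headroom_error")
  expect_error(level_spec(0), class = "auditest_bad_level_spec")
  expect_error(level_spec(3), class = "auditest_bad_level_spec")
})

test_that("mix_at_snr realizes the requested SNR exactly", {
  set.seed(21)
  speech <- calibrate_rms(waveform(rnorm(4000), 16000), level_spec(-25))
  noise <- calibrate_rms(waveform(rnorm(4000), 16000), level_spec(-25))
  for (snr in c(0, 5, 20, -7.3)) {
    mixed <- mix_at_snr(speech, noise, snr)
    g <- attr(mixed, "noise_gain")
    expect_equal(g, 10^(-snr / 20), tolerance = 1e-12)
    realized <- 20 * log10(sqrt(mean(speech$samples^2)) /
                             sqrt(mean((g * noise$samples)^2)))
    expect_equal(realized, snr, tolerance = 1e-9)
  }
})

test_that("mix_at_snr crops long noise reproducibly and rejects bad input", {
  set.seed(22)
  speech <- waveform(rnorm(1000), 16000)
  long_noise <- waveform(rnorm(5000), 16000)
  m1 <- mix_at_snr(speech, long_noise, 5, seed = 7)
  m2 <- mix_at_snr(speech, long_noise, 5, seed = 7)
  expect_identical(m1$samples, m2$samples)
  expect_length(m1$samples, 1000)
  short <- waveform(rnorm(10), 16000)
  expect_error(mix_at_snr(speech, short, 0), class = "auditest_bad_argument")
  expect_error(mix_at_snr(speech, waveform(rnorm(1000), 8000), 0),
               class = "auditest_rate_mismatch")
  expect_error(mix_at_snr(speech, waveform(numeric(1000) , 16000), 0),
               class = "auditest_undefined_level")
})

test_that("prepend_silence pads exact zero counts and preserves samples", {
  set.seed(31)
  w <- waveform(rnorm(100), 44100)
  p <- prepend_silence(w, 200)
  expect_length(p$samples, 100 + 8820)
  expect_identical(p$samples[1:8820], numeric(8820))
  expect_identical(p$samples[8821:8920], w$samples)
  w16 <- waveform(rnorm(10), 16000)
  expect_length(prepend_silence(w16, 200)$samples, 10 + 3200)
  expect_identical(prepend_silence(w, 0)$samples, w$samples)
  expect_error(prepend_silence(w, -1), class = "auditest_bad_argument")
})

test_that("digit tokens are deterministic, calibrated, and pairwise distinct", {
  toks <- lapply(0:9, function(d) synth_digit_token(d, 16000))
  for (tok in toks) expect_equal(rms_dbfs(tok), -25, tolerance = 1e-9)
  expect_identical(synth_digit_token(4, 16000, seed = 9)$samples,
                   synth_digit_token(4, 16000, seed = 9)$samples)
  # all 45 pairs: peak normalized cross-correlation below 0.9
  worst <- 0
  for (i in 1:9) {
    for (j in (i + 1):10) {
      r <- auditest:::ncc_lags(toks[[i]]$samples, toks[[j]]$samples, 0)
      worst <- max(worst, abs(r))
    }
  }
  expect_lt(worst, 0.9)
  expect_error(synth_digit_token(10, 16000), class = "auditest_bad_argument")
})

test_that("speech-shaped noise matches the reference spectrum and level", {
  set.seed(41)
  lp <- calibrate_rms(
    waveform(as.numeric(signal::filter(signal::butter(4, 0.125),
                                       rnorm(16000))), 16000),
    level_spec(-25))
  ssn <- synth_speech_shaped_noise(lp, 1, seed = 2)
  expect_equal(rms_dbfs(ssn), -25, tolerance = 1e-9)
  band_ratio <- function(w) {
    mag <- Mod(stats::fft(w$samples))
    n <- length(mag)
    f <- (0:(n %/% 2 - 1)) * w$sample_rate / n
    half <- mag[seq_len(n %/% 2)]
    10 * log10(sum(half[f < 1000]^2) / sum(half[f >= 1000]^2))
  }
  expect_equal(band_ratio(ssn), band_ratio(lp), tolerance = 1)
  # stationarity: every 250 ms window within ±3 dB of the global RMS
  win <- 0.25 * 16000
  starts <- seq(1, length(ssn$samples) - win, by = win)
  wrms <- vapply(starts, function(i) {
    10 * log10(mean(ssn$samples[i:(i + win - 1)]^2))
  }, numeric(1))
  expect_true(all(abs(wrms - rms_dbfs(ssn)) < 3))
  # determinism
  expect_identical(synth_speech_shaped_noise(lp, 0.5, seed = 3)$samples,
                   synth_speech_shaped_noise(lp, 0.5, seed = 3)$samples)
  expect_error(synth_speech_shaped_noise(lp, 0),
               class = "auditest_bad_argument")
})

test_that("white reference yields spectrally flat shaped noise", {
  set.seed(42)
  white <- calibrate_rms(waveform(rnorm(16000), 16000), level_spec(-25))
  ssn <- synth_speech_shaped_noise(white, 1, seed = 5)
  mag <- Mod(stats::fft(ssn$samples))
  n <- length(mag)
  half <- mag[seq_len(n %/% 2)]
  thirds <- split(half, cut(seq_along(half), 3))
  energies <- vapply(thirds, function(x) 10 * log10(mean(x^2)), numeric(1))
  expect_lt(max(energies) - min(energies), 1.5)
})

test_that("stripes stimuli are directional, deterministic and density-monotone", {
  sp <- function(d, dir) stripes_spec(d, dir, f_low_hz = 250,
                                      f_high_hz = 6000)
  for (seed in 1:5) {
    up <- synth_stripes(sp(1.1, "up"), 16000, seed = seed)
    dn <- synth_stripes(sp(1.1, "down"), 16000, seed = seed)
    expect_gt(oracle_sweep_slope_sign(up), 0)
    expect_lt(oracle_sweep_slope_sign(dn), 0)
  }
  expect_identical(synth_stripes(sp(2, "up"), 16000, seed = 4)$samples,
                   synth_stripes(sp(2, "up"), 16000, seed = 4)$samples)
  # higher density -> the ridge traverses a fixed mid frequency more often;
  # track the single-component ridge and count upward crossings of the
  # geometric band center
  crossing_count <- function(density) {
    w <- synth_stripes(stripes_spec(density, "up", f_low_hz = 250,
                                    f_high_hz = 6000, n_components = 1L),
                       16000, seed = 1)
    x <- w$samples
    frame <- 256L; hop <- 128L
    n_frames <- (length(x) - frame) %/% hop + 1L
    peak <- vapply(seq_len(n_frames), function(i) {
      seg <- x[((i - 1L) * hop + 1L):((i - 1L) * hop + frame)]
      which.max(Mod(stats::fft(seg))[2:(frame %/% 2)])
    }, numeric(1))
    mid_bin <- sqrt(250 * 6000) * frame / 16000
    sum(diff(peak > mid_bin) == 1)
  }
  expect_gt(crossing_count(2.0), crossing_count(1.1))
  expect_error(stripes_spec(0.9), class = "auditest_bad_argument")
  expect_error(synth_stripes(stripes_spec(1.5, f_high_hz = 9000), 16000),
               class = "auditest_bad_argument")
})

test_that("a DIN trial mixes calibrated digit speech with matched noise", {
  spec <- din_trial_spec(c(3, 5, 8), snr_db = 0)
  trial <- synth_din_trial(spec, sample_rate = 16000, seed = 2)
  expect_s3_class(trial, "waveform")
  # at 0 dB SNR the noise gain is ~1 (the crop changes the segment RMS
  # slightly; the realized SNR over the segment is exact by contract)
  expect_equal(attr(trial, "noise_gain"), 1, tolerance = 0.05)
  expect_error(din_trial_spec(c(1, 2), 0), class = "auditest_bad_argument")
  expect_error(din_trial_spec(c(1, 2, 3), 25),
               class = "auditest_bad_argument")
})
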