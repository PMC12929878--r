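# Independent brute-force oracles, coded straightforwardly and separately
# from the package's engine so the two can be compared bit-exactly.

# Trace simulator for a transformed up-down staircase. Plain procedural
# code: counters, an explicit reversal list, sequential arithmetic.
oracle_staircase_trace <- function(responses, n_up, n_down, sched_thresholds,
                                   sched_steps, start, lo, hi, harder_sign,
                                   stop_type, stop_n) {
  level <- start
  levels <- numeric(0)
  rev_levels <- numeric(0)
  cc <- 0L
  ci <- 0L
  last_dir <- 0L
  finished <- FALSE
  for (resp in responses) {
    if (finished) break
    levels <- c(levels, level)
    dir <- 0L
    if (resp) {
      cc <- cc + 1L
      ci <- 0L
      if (cc == n_up) {
        dir <- 1L
        cc <- 0L
      }
    } else {
      ci <- ci + 1L
      cc <- 0L
      if (ci == n_down) {
        dir <- -1L
        ci <- 0L
      }
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) {
        rev_levels <- c(rev_levels, level)
      }
      step <- sched_steps[max(which(sched_thresholds <= length(rev_levels)))]
      level <- level + dir * harder_sign * step
      if (level < lo) level <- lo
      if (level > hi) level <- hi
      last_dir <- dir
    }
    if (stop_type == "trials" && length(levels) >= stop_n) finished <- TRUE
    if (stop_type == "reversals" && length(rev_levels) >= stop_n) {
      finished <- TRUE
    }
  }
  list(levels = levels, reversal_levels = rev_levels, finished = finished)
}

oracle_din_trace <- function(responses) {
  oracle_staircase_trace(responses, n_up = 1L, n_down = 1L,
                         sched_thresholds = 0L, sched_steps = 2,
                         start = 0, lo = -20, hi = 20, harder_sign = -1,
                         stop_type = "trials", stop_n = 24L)
}

oracle_stripes_trace <- function(responses) {
  oracle_staircase_trace(responses, n_up = 2L, n_down = 1L,
                         sched_thresholds = c(0L, 4L),
                         sched_steps = c(0.5, 0.2),
                         start = 1.1, lo = 1, hi = 20, harder_sign = +1,
                         stop_type = "reversals", stop_n = 8L)
}

# dominant-ridge slope sign of a spectrogram: +1 for upward sweeps.
# Small STFT built directly on stats::fft, independent of the synthesizer.
oracle_sweep_slope_sign <- function(w, frame = 512L, hop = 256L) {
  x <- w$samples
  n_frames <- (length(x) - frame) %/% hop + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(frame - 1)) / (frame - 1))
  peak_bin <- vapply(seq_len(n_frames), function(i) {
    seg <- x[((i - 1L) * hop + 1L):((i - 1L) * hop + frame)] * win
    mag <- Mod(stats::fft(seg))[2:(frame %/% 2)]
    which.max(mag)
  }, numeric(1))
  d <- diff(log(peak_bin))
  # wrap-around jumps are large and opposite-signed; the typical step sign
  # is robustly read from the median
  sign(stats::median(d[d != 0]))
}

rand_waveform <- function(n = 400L, rate = 16000L) {
  waveform(rnorm(n), rate)
}
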