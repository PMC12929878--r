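#' Mono audio waveform
#'
#' The unit every signal operation in the package consumes and produces:
#' a vector of real-valued samples on a full-scale convention of ±1.0
#' (0 dB FS = amplitude 1.0) together with its sampling rate in Hz.
#'
#' @param samples Numeric vector of samples, full scale ±1.0.
#' @param sample_rate Sampling rate in Hz (positive integer-valued scalar).
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)), 16000)
#' rms_dbfs(w)
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort("`samples` must be a numeric vector with at least one sample.",
          class = "auditest_bad_waveform")
  }
  if (anyNA(samples)) {
    abort("`samples` must not contain NA.", class = "auditest_bad_waveform")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 0 || sample_rate != round(sample_rate)) {
    abort("`sample_rate` must be a single positive integer-valued number (Hz).",
          class = "auditest_bad_waveform")
  }
  structure(
    list(samples = as.double(samples), sample_rate = as.double(sample_rate)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples @ %g Hz, %.3f s, peak %.4g>\n",
    length(x$samples), x$sample_rate, duration_s(x), max(abs(x$samples))
  ))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Length in seconds.
#' @export
duration_s <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$sample_rate
}

#' @export
as_tibble.waveform <- function(x, ...) {
  tibble(
    time_s = (seq_along(x$samples) - 1) / x$sample_rate,
    amplitude = x$samples
  )
}

#' @export
tidy.waveform <- function(x, ...) as_tibble(x)

is_waveform <- function(x) inherits(x, "waveform")

check_waveform <- function(w, arg = "w") {
  if (!is_waveform(w)) {
    abort(sprintf("`%s` must be a waveform object.", arg),
          class = "auditest_bad_waveform")
  }
  invisible(w)
}

#' Plot a waveform as amplitude over time
#'
#' @param object A [waveform()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.waveform <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (full scale ±1)") +
    ggplot2::theme_minimal()
}
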