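#' Read a mono WAV file
#'
#' Supports linear PCM at 16 or 24 bits and IEEE float32, mono only
#' (stereo files are rejected with a clear error). Integer PCM is scaled
#' onto the internal ±1.0 full-scale convention; float data is read
#' losslessly.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("WAV file not found: %s", path), class = "auditest_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little") # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("Not a RIFF/WAVE file: %s", path),
          class = "auditest_io_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little")
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2) # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("Missing fmt/data chunk in %s", path),
          class = "auditest_io_error")
  }
  if (fmt$n_channels != 1L) {
    abort(sprintf("Only mono WAV is supported; %s has %d channels.",
                  path, fmt$n_channels),
          class = "auditest_io_error")
  }
  samples <- switch(
    as.character(fmt$audio_format),
    "1" = { # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2, 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        b <- as.integer(data_raw)
        n <- length(b) %/% 3
        idx <- 3 * (seq_len(n) - 1)
        v <- b[idx + 1] + 256 * b[idx + 2] + 65536 * b[idx + 3]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        abort(sprintf("Unsupported PCM bit depth %d in %s", fmt$bits, path),
              class = "auditest_io_error")
      }
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4, 4,
                  endian = "little"),
    abort(sprintf("Unsupported WAV audio format code %d in %s",
                  fmt$audio_format, path),
          class = "auditest_io_error")
  )
  waveform(samples, fmt$sample_rate)
}

#' Write a waveform to a mono WAV file
#'
#' Float32 export is lossless for the internal representation; integer PCM
#' export quantizes by rounding with no dithering, keeping levels
#' bit-reproducible.
#'
#' @param w A [waveform()]; samples must lie within ±1.0.
#' @param path Output path.
#' @param format One of `"float32"` (default), `"pcm16"`, `"pcm24"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("float32", "pcm16", "pcm24")) {
  check_waveform(w)
  format <- match.arg(format)
  if (max(abs(w$samples)) > 1) {
    abort("Samples exceed full scale; calibrate before writing.",
          class = "auditest_headroom_error")
  }
  n <- length(w$samples)
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
    payload <- writeBin(w$samples, raw(), size = 4, endian = "little")
  } else if (format == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    v <- as.integer(pmin(pmax(round(w$samples * 32768), -32768), 32767))
    payload <- writeBin(v, raw(), size = 2, endian = "little")
  } else {
    fmt_code <- 1L; bits <- 24L
    v <- pmin(pmax(round(w$samples * 8388608), -8388608), 8388607)
    v <- ifelse(v < 0, v + 16777216, v)
    bytes <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    payload <- as.raw(as.vector(bytes))
  }
  block_align <- bits %/% 8L
  byte_rate <- as.integer(w$sample_rate) * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little") # mono
  writeBin(as.integer(w$sample_rate), con, 4, endian = "little")
  writeBin(byte_rate, con, 4, endian = "little")
  writeBin(as.integer(block_align), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(payload), con, 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}
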