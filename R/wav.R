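# Minimal RIFF/WAVE reader and writer.  Supports the PCM encodings used by
# the corpora this package emulates (16/24-bit integer and 32/64-bit float),
# with channel downmix and rational-rate resampling on load.  None of the
# audio packages this would normally lean on are part of the supported
# dependency set, so the container format is parsed directly; it is a small,
# fully specified chunk format.

#' Read a WAV file
#'
#' Reads a PCM or IEEE-float WAV file, downmixes to mono by channel
#' averaging, and optionally resamples to a target rate.  Samples are
#' returned as doubles in \[-1, 1\].
#'
#' @param path file path.
#' @param to_rate target sampling rate in Hz, or `NULL` to keep the file's
#'   native rate.  Defaults to 16 kHz, the canonical processing rate.
#' @return a list with elements `samples` (numeric vector) and `rate`.
#' @export
read_wav <- function(path, to_rate = 16000) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        rate     = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
      if (fmt$format == -2L && size >= 40) {  # WAVE_FORMAT_EXTENSIBLE
        fmt$format <- readBin(body[25:26], "integer", 1, 2, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)

  x <- decode_pcm(data_raw, fmt$format, fmt$bits)
  if (fmt$channels > 1) {
    n <- floor(length(x) / fmt$channels)
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels,
                         byrow = TRUE))
  }
  rate <- fmt$rate
  if (!is.null(to_rate) && to_rate != rate) {
    x <- resample_audio(x, rate, to_rate)
    rate <- to_rate
  }
  list(samples = x, rate = rate)
}

decode_pcm <- function(raw, format, bits) {
  if (format == 1L) {
    if (bits == 16L) {
      readBin(raw, "integer", length(raw) / 2, 2, signed = TRUE,
              endian = "little") / 32768
    } else if (bits == 24L) {
      n <- length(raw) / 3
      b <- matrix(as.integer(raw), nrow = 3)
      v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (bits == 8L) {
      (as.integer(raw) - 128) / 128
    } else {
      stop("unsupported PCM bit depth: ", bits)
    }
  } else if (format == 3L) {
    if (bits == 32L) {
      readBin(raw, "double", length(raw) / 4, 4, endian = "little")
    } else if (bits == 64L) {
      readBin(raw, "double", length(raw) / 8, 8, endian = "little")
    } else {
      stop("unsupported float bit depth: ", bits)
    }
  } else {
    stop("unsupported WAV encoding code: ", format)
  }
}

# Rational-rate polyphase resampling (signal::resample) with the ratio
# reduced by the gcd of the two rates.
resample_audio <- function(x, from, to) {
  g <- ratio_gcd(to, from)
  as.numeric(signal::resample(x, to / g, from / g))
}

ratio_gcd <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Write a mono WAV file (16-bit PCM)
#'
#' @param samples numeric vector in \[-1, 1\] (clipped if outside).
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  pcm <- as.integer(round(clamp(samples, -1, 1) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")          # PCM
  writeBin(1L, con, 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
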