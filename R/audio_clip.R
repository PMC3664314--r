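#' Construct an audio clip
#'
#' Light container for a mono audio signal.  Samples outside \[-1, 1\] are
#' peak-normalized on construction.
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in Hz.
#' @param clip_id identifier used in feature tables and logs.
#' @param domain domain tag, one of `"sound"`, `"music"`, `"speech_spont"`,
#'   `"speech_enacted"`, `"synthetic"`.
#' @return an object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate, clip_id = "clip", domain = "synthetic") {
  if (length(samples) == 0) stop("audio_clip: samples must be non-empty")
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("audio_clip: samples must be finite numeric")
  }
  if (!is.numeric(rate) || rate <= 0) stop("audio_clip: rate must be > 0")
  domain <- match.arg(domain, c("sound", "music", "speech_spont",
                                "speech_enacted", "speech", "synthetic"))
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak
  structure(list(samples = as.numeric(samples), rate = rate,
                 clip_id = as.character(clip_id), domain = domain),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s' [%s]: %.2f s @ %d Hz>\n",
              x$clip_id, x$domain, length(x$samples) / x$rate,
              as.integer(x$rate)))
  invisible(x)
}

#' Load a WAV file as an audio clip
#'
#' @param path WAV file path.
#' @param domain domain tag (see [audio_clip()]).
#' @param to_rate processing rate; see [read_wav()].
#' @return an `audio_clip`.
#' @export
load_clip <- function(path, domain = "synthetic", to_rate = 16000) {
  w <- read_wav(path, to_rate = to_rate)
  audio_clip(w$samples, w$rate,
             clip_id = sub("\\.wav$", "", basename(path), ignore.case = TRUE),
             domain = domain)
}

as_clip <- function(x, rate = NULL) {
  if (inherits(x, "audio_clip")) return(x)
  if (is.null(rate)) stop("rate required for bare numeric input")
  audio_clip(x, rate)
}
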