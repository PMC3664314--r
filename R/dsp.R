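# Frame-level DSP primitives shared by the descriptor extractors.

taper_window <- function(n, type = c("hamming", "hann", "rectangular")) {
  type <- match.arg(type)
  k <- seq_len(n) - 1
  switch(type,
         hamming     = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann        = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         rectangular = rep(1, n))
}

#' Slice a clip into overlapping windowed frames
#'
#' Frames start at the first sample and advance by `hop`; the trailing
#' remainder shorter than one window is dropped, so the frame count is
#' `floor((n_samples - win) / hop) + 1`.
#'
#' @param clip an [audio_clip()] (or numeric vector with `rate` given).
#' @param win_len window length in seconds.
#' @param hop hop size in seconds; must satisfy `win_len >= hop > 0`.
#' @param window taper name: `"hamming"`, `"hann"` or `"rectangular"`.
#' @param rate sampling rate, only for bare numeric input.
#' @return list with `frames` (win x n_frames matrix, tapered), `raw`
#'   (untapered), `times` (frame centers, s), `win_samples`, `hop_samples`.
#' @export
frame_signal <- function(clip, win_len = 0.025, hop = 0.010,
                         window = "hamming", rate = NULL) {
  clip <- as_clip(clip, rate)
  if (!(win_len >= hop && hop > 0)) stop("need win_len >= hop > 0")
  x <- clip$samples
  wl <- round(win_len * clip$rate)
  hp <- max(1L, round(hop * clip$rate))
  if (length(x) < wl) {
    stop(sprintf("clip '%s' (%d samples) is shorter than one %d-sample window",
                 clip$clip_id, length(x), wl))
  }
  nf <- floor((length(x) - wl) / hp) + 1
  idx <- outer(seq_len(wl), (seq_len(nf) - 1L) * hp, "+")
  raw <- matrix(x[idx], nrow = wl, ncol = nf)
  w <- taper_window(wl, window)
  list(frames = raw * w, raw = raw,
       times = ((seq_len(nf) - 1L) * hp + (wl - 1) / 2) / clip$rate,
       win_samples = wl, hop_samples = hp)
}

# Magnitude spectra of all frames at once; rows are bins 0..nfft/2.
frame_spectra <- function(frames, nfft = NULL) {
  wl <- nrow(frames)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(wl))
  padded <- matrix(0, nfft, ncol(frames))
  padded[seq_len(wl), ] <- frames
  sp <- stats::mvfft(padded)
  Mod(sp[seq_len(nfft / 2 + 1), , drop = FALSE])
}

# Memoized heavy constants (filterbanks, bases, candidate grids).
.dsp_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .dsp_cache)) {
    assign(key, build(), envir = .dsp_cache)
  }
  get(key, envir = .dsp_cache)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel-spaced filterbank, rows = bands, columns = FFT bins.
mel_filterbank <- function(n_bands, nfft, rate, fmin = 0, fmax = rate / 2) {
  bins <- seq(0, nfft / 2) * rate / nfft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_bands + 2))
  fb <- matrix(0, n_bands, length(bins))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; ce <- edges[b + 1]; hi <- edges[b + 2]
    up <- (bins - lo) / max(ce - lo, EPS)
    dn <- (hi - bins) / max(hi - ce, EPS)
    fb[b, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# Classic equal-loudness preemphasis curve evaluated at bin frequencies,
# used to weight the power spectrum before the auditory filterbank.
equal_loudness_weight <- function(freqs) {
  f2 <- freqs^2
  w <- (f2 / (f2 + 1.6e5))^2 * (f2 + 1.44e6) / (f2 + 9.61e6)
  w / max(w)
}

# Orthonormal DCT-II basis (rows = coefficients 0..n_out-1).
dct_basis <- function(n_in, n_out) {
  m <- outer(0:(n_out - 1), seq_len(n_in) - 0.5,
             function(k, j) cos(pi * k * j / n_in))
  m * sqrt(2 / n_in)
}

# Band-pass filtering of each row's trajectory: FIR differentiator
# (0.2, 0.1, 0, -0.1, -0.2) followed by a leaky integrator pole.
# A constant trajectory maps to zero once the filter has settled.
rasta_filter <- function(logbands, pole = 0.94) {
  num <- c(0.2, 0.1, 0, -0.1, -0.2)
  out <- logbands
  nf <- ncol(logbands)
  for (b in seq_len(nrow(logbands))) {
    x <- logbands[b, ]
    xp <- c(rep(x[1], 4), x)
    fir <- num[1] * xp[5:(nf + 4)] + num[2] * xp[4:(nf + 3)] +
      num[4] * xp[2:(nf + 1)] + num[5] * xp[1:nf]
    out[b, ] <- as.numeric(stats::filter(fir, pole, method = "recursive"))
  }
  out
}
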