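# Fundamental frequency by subharmonic summation with Viterbi smoothing,
# plus voice-quality descriptors (HNR, jitter, shimmer) on voiced stretches.

shs_weight_matrix <- function(config, nbins, bin_hz) {
  key <- sprintf("shs_%g_%g_%d_%d_%g_%d_%g", config$f0_range[1],
                 config$f0_range[2], config$n_f0_candidates, nbins,
                 bin_hz, config$shs_harmonics, config$shs_decay)
  cached(key, function() build_shs_matrix(config, nbins, bin_hz))
}

build_shs_matrix <- function(config, nbins, bin_hz) {
  cand <- exp(seq(log(config$f0_range[1]), log(config$f0_range[2]),
                  length.out = config$n_f0_candidates))
  W <- matrix(0, length(cand), nbins)
  for (h in seq_len(config$shs_harmonics)) {
    wgt <- config$shs_decay^(h - 1)
    pos <- cand * h / bin_hz          # fractional bin index (0-based)
    lo <- floor(pos)
    frac <- pos - lo
    ok <- lo + 2 <= nbins
    i <- which(ok)
    W[cbind(i, lo[i] + 1L)] <- W[cbind(i, lo[i] + 1L)] + wgt * (1 - frac[i])
    W[cbind(i, lo[i] + 2L)] <- W[cbind(i, lo[i] + 2L)] + wgt * frac[i]
  }
  list(candidates = cand, W = W)
}

#' Per-frame fundamental frequency and voicing probability
#'
#' Pitch candidates on a geometric grid are scored by subharmonic
#' summation of the gain-normalized magnitude spectrum (60 ms window); the
#' track is smoothed by a Viterbi path with a per-octave jump penalty.
#' Voicing probability is the unbiased normalized autocorrelation of the
#' raw frame at the tracked period; F0 is 0 where it falls below the
#' configured threshold.  Clips shorter than one pitch window are treated
#' as entirely unvoiced.
#'
#' @param clip an [audio_clip()] at the canonical rate.
#' @param config an [lld_config()].
#' @return list with per-pitch-frame `f0` (Hz, 0 when unvoiced), `vprob`,
#'   `hnr` (dB, 0 when unvoiced), `voiced`, and `n_frames`.
#' @export
f0_voicing <- function(clip, config = lld_config()) {
  clip <- as_clip(clip)
  x <- clip$samples
  wl <- round(config$f0_win_len * config$rate)
  if (length(x) < wl) {
    return(list(f0 = numeric(0), vprob = numeric(0), hnr = numeric(0),
                voiced = logical(0), n_frames = 0L, hop_multiple = 2L))
  }
  # pitch varies slowly: analyse on twice the common hop and on the
  # 2x-decimated signal (all pitch information, including the subharmonic
  # summation terms up to 5 x 600 Hz, lies below the decimated Nyquist);
  # the spectral resolution is unchanged
  hop_mult <- 2L
  dec <- 2L
  xd <- x[seq(1, length(x), dec)]
  fr <- frame_signal(xd, config$f0_win_len, config$hop * hop_mult, "hann",
                     rate = config$rate / dec)
  mag <- frame_spectra(fr$frames)
  nf <- ncol(mag)
  bin_hz <- (config$rate / dec) / ((nrow(mag) - 1) * 2)

  shs <- shs_weight_matrix(config, nrow(mag), bin_hz)
  m_hat <- mag * rep(1 / pmax(colSums(mag), EPS), each = nrow(mag))
  scores <- shs$W %*% m_hat

  path <- viterbi_path(scores, shs$candidates, config$viterbi_jump_cost)
  f0_raw <- shs$candidates[path]

  vp <- cpp_acf_voicing(xd, fr$win_samples, fr$hop_samples, nf,
                        (config$rate / dec) / f0_raw)
  voiced <- vp >= config$voicing_threshold
  r <- clamp(vp, 1e-6, 1 - 1e-6)
  hnr <- 10 * log10(r / (1 - r)) * voiced
  list(f0 = f0_raw * voiced, vprob = vp, hnr = hnr, voiced = voiced,
       n_frames = nf, hop_multiple = 2L)
}

viterbi_path <- function(scores, candidates, jump_cost) {
  em <- log(scores + 1e-6)
  if (ncol(em) == 1) return(which.max(em[, 1]))
  trans <- jump_cost * abs(outer(log2(candidates), log2(candidates), "-"))
  cpp_viterbi(em, trans)
}

# Pure-R reference for the compiled Viterbi kernel (kept for tests).
viterbi_path_ref <- function(scores, candidates, jump_cost) {
  nc <- nrow(scores); nf <- ncol(scores)
  em <- log(scores + 1e-6)
  if (nf == 1) return(which.max(em[, 1]))
  trans <- jump_cost * abs(outer(log2(candidates), log2(candidates), "-"))
  delta <- em[, 1]
  psi <- matrix(0L, nc, nf)
  for (t in 2:nf) {
    m <- delta - trans                 # m[i, j] = delta_i - cost(i -> j)
    best <- max.col(t(m), ties.method = "first")
    delta <- m[cbind(best, seq_len(nc))] + em[, t]
    psi[, t] <- best
  }
  path <- integer(nf)
  path[nf] <- which.max(delta)
  for (t in nf:2) path[t - 1] <- psi[path[t], t]
  path
}

# Map the pitch track (longer window, coarser hop) onto the spectral
# 10 ms grid by nearest frame center, replicating edges.
align_f0_track <- function(f0v, n_frames, config = lld_config()) {
  if (f0v$n_frames == 0) {
    z <- numeric(n_frames)
    return(list(f0 = z, vprob = z, hnr = z, voiced = logical(n_frames)))
  }
  hp_s <- round(config$hop * config$rate)
  wl_s <- round(config$win_len * config$rate)
  hp_f <- hp_s * f0v$hop_multiple
  wl_f <- round(config$f0_win_len * config$rate)
  centers_s <- (seq_len(n_frames) - 1) * hp_s + wl_s / 2
  idx <- clamp(round((centers_s - wl_f / 2) / hp_f) + 1L, 1L, f0v$n_frames)
  list(f0 = f0v$f0[idx], vprob = f0v$vprob[idx], hnr = f0v$hnr[idx],
       voiced = f0v$voiced[idx])
}

#' Voice-quality descriptors: jitter, shimmer
#'
#' Pitch-period markers are located by peak picking with parabolic
#' sub-sample refinement on every voiced stretch (runs of consecutive
#' voiced frames).  Jitter is the mean absolute consecutive period
#' difference over the mean period; jitter delta applies the same measure
#' to second-order period differences; shimmer is the analogous measure on
#' refined marker amplitudes.  Stretches with fewer than three detected
#' periods contribute zeros, as do unvoiced frames.
#'
#' @param clip an [audio_clip()] at the canonical rate.
#' @param f0_track aligned track from [align_f0_track()] (or the output of
#'   [f0_voicing()] when frame grids already agree).
#' @param config an [lld_config()].
#' @return list of per-frame `jitter_local`, `jitter_delta`,
#'   `shimmer_local`.
#' @export
voice_quality <- function(clip, f0_track, config = lld_config()) {
  clip <- as_clip(clip)
  x <- clip$samples
  nf <- length(f0_track$f0)
  hp <- max(1L, round(config$hop * config$rate))
  wl <- round(config$win_len * config$rate)
  jit <- jitd <- shim <- numeric(nf)
  if (nf == 0 || !any(f0_track$voiced)) {
    return(list(jitter_local = jit, jitter_delta = jitd, shimmer_local = shim))
  }
  r <- rle(f0_track$voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (s in which(r$values & r$lengths >= 3)) {
    t0 <- starts[s]; t1 <- ends[s]
    s0 <- (t0 - 1) * hp + 1
    s1 <- min(length(x), (t1 - 1) * hp + wl)
    f0m <- stats::median(f0_track$f0[t0:t1])
    if (f0m <= 0) next
    mk <- cpp_period_markers(x[s0:s1], config$rate / f0m)
    if (mk$n < 4) next                         # < 3 periods
    P <- diff(mk$pos)
    A <- mk$amp
    mp <- mean(P)
    if (mp < EPS) next
    jit[t0:t1] <- mean(abs(diff(P))) / mp
    jitd[t0:t1] <- if (length(P) >= 3) mean(abs(diff(P, differences = 2))) / mp else 0
    ma <- mean(abs(A))
    shim[t0:t1] <- if (ma > EPS) mean(abs(diff(A))) / ma else 0
  }
  list(jitter_local = jit, jitter_delta = jitd, shimmer_local = shim)
}

# Successive waveform peaks about one estimated period apart, refined to
# sub-sample precision by parabolic interpolation.
period_markers <- function(seg, period) {
  n <- length(seg)
  first_hi <- min(n, max(3, ceiling(1.5 * period)))
  i <- which.max(seg[seq_len(first_hi)])
  cap <- ceiling(n / (0.7 * period)) + 2L
  pos <- amp <- numeric(cap)
  k <- 0L
  while (TRUE) {
    p <- refine_peak(seg, i)
    k <- k + 1L
    pos[k] <- p$pos; amp[k] <- p$amp
    lo <- round(i + 0.7 * period); hi <- round(i + 1.3 * period)
    if (hi > n) break
    i <- lo - 1L + which.max(seg[lo:hi])
  }
  list(pos = pos[seq_len(k)], amp = amp[seq_len(k)], n = k)
}

refine_peak <- function(seg, i) {
  n <- length(seg)
  if (i <= 1 || i >= n) return(list(pos = i, amp = seg[i]))
  y1 <- seg[i - 1]; y2 <- seg[i]; y3 <- seg[i + 1]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < EPS) return(list(pos = i, amp = y2))
  d <- clamp(0.5 * (y1 - y3) / den, -1, 1)
  list(pos = i + d, amp = y2 - 0.25 * (y1 - y3) * d)
}
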