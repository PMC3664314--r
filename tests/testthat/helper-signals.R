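# Signal fixtures, generated in code.

tone_clip <- function(freq, dur = 1, rate = 16000, amp = 0.5, id = "tone") {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  audio_clip(amp * sin(2 * pi * freq * t), rate, clip_id = id)
}

# harmonic complex with optional fractional per-cycle period jitter and
# amplitude shimmer, synthesized by continuous phase accumulation so the
# cycle lengths are not quantized to whole samples
harmonic_clip <- function(f0, dur = 1, rate = 16000, n_harm = 5, amp = 0.5,
                          period_jitter = 0, amp_jitter = 0, seed = 1,
                          id = "harm") {
  n <- round(dur * rate)
  t0 <- rate / f0
  x <- with_seed(seed, {
    n_cyc <- ceiling(n / (t0 * (1 - max(period_jitter, 0.001)))) + 3
    tp <- t0 * (1 + stats::runif(n_cyc, -period_jitter, period_jitter))
    bounds <- c(0, cumsum(tp))
    cyc_of <- findInterval(seq_len(n) - 1, bounds)
    inst <- (rate / tp)[cyc_of]            # instantaneous frequency, Hz
    ph <- 2 * pi * cumsum(inst) / rate
    sig <- 0
    for (h in seq_len(n_harm)) sig <- sig + sin(h * ph) / h
    gains <- (1 + stats::runif(n_cyc, -amp_jitter, amp_jitter))[cyc_of]
    sig * gains
  })
  audio_clip(amp * x / max(abs(x)), rate, clip_id = id)
}

noise_clip <- function(dur = 1, rate = 16000, amp = 0.25, seed = 1,
                       id = "noise") {
  x <- with_seed(seed, stats::rnorm(round(dur * rate)))
  audio_clip(amp * x / max(abs(x)), rate, clip_id = id)
}

# small feature-level domain list with a known planted structure
tiny_domains <- function(n = 60, d = 40, s = 5, r = 0.7, seed = 1,
                         flip = NULL) {
  gen_feature_level(n_domains = 3, n_per_domain = n, d = d, s = s,
                    r_planted = r, flip_domain = flip, seed = seed)
}
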