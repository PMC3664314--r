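cfg <- lld_config()

test_that("framing follows the count formula and tapers frames", {
  cl <- tone_clip(200, dur = 1)
  fr <- frame_signal(cl, 0.025, 0.010)
  expect_equal(ncol(fr$frames), 98)   # floor((16000 - 400) / 160) + 1
  one <- frame_signal(tone_clip(200, dur = 0.025), 0.025, 0.010)
  expect_equal(ncol(one$frames), 1)
  silent <- audio_clip(rep(0, 4000), 16000)
  expect_true(all(frame_signal(silent, 0.025, 0.010)$frames == 0))
  expect_error(frame_signal(audio_clip(rep(0, 100), 16000), 0.025, 0.010),
               "shorter than one")
  expect_error(frame_signal(cl, 0.005, 0.010), "win_len >= hop")
})

test_that("auditory spectrum localizes a pure tone and RASTA removes DC", {
  cl <- tone_clip(1000, dur = 0.5)
  mag <- frame_spectra(frame_signal(cl, 0.025, 0.010)$frames)
  au <- auditory_spectrum(mag, cfg)
  expect_true(all(au$bands >= 0))
  expect_equal(nrow(au$bands), 26)
  # arg-max band must be the band whose center is nearest 1 kHz
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(8000), length.out = 28))
  centers <- edges[2:27]
  expect_equal(unname(which.max(rowMeans(au$bands))),
               which.min(abs(centers - 1000)), tolerance = 1)
  # stationary input: band trajectories constant -> RASTA decays to ~0
  # (log-band values are O(10), so this bound is far below signal scale)
  tail_frames <- au$rasta[, 40:ncol(au$rasta), drop = FALSE]
  expect_lt(max(abs(tail_frames)), 1e-6)
})

test_that("loudness is zero for silence and monotone in gain", {
  silent <- audio_clip(rep(0, 8000), 16000)
  msil <- extract_lld(silent, cfg)
  expect_true(all(msil$values[, "loudness"] < 1e-3))
  expect_true(all(msil$values[, "rms_energy"] == 0))
  expect_true(all(msil$values[, "f0"] == 0))

  cl <- tone_clip(300, dur = 0.5, amp = 0.3)
  cl2 <- audio_clip(cl$samples * 2, cl$rate)
  l1 <- extract_lld(cl, cfg)$values[, "loudness"]
  l2 <- extract_lld(cl2, cfg)$values[, "loudness"]
  expect_true(all(l2 >= l1))
  expect_gt(mean(l2), mean(l1))

  # white noise and a tone at matched RMS both produce positive loudness
  nz <- noise_clip(0.5, amp = 0.3 / sqrt(2) / 0.25, seed = 2)
  expect_gt(mean(extract_lld(nz, cfg)$values[, "loudness"]), 0)
})

test_that("RMS and zero-crossing rate match closed forms", {
  a <- 0.4
  cl <- tone_clip(100, dur = 1, amp = a)
  fr <- frame_signal(cl, 0.025, 0.010)
  en <- rms_energy_zcr(fr$raw)
  expect_equal(median(en$rms), a / sqrt(2), tolerance = 0.01)
  # 100 Hz -> 200 sign changes per second -> 5 per 25 ms frame
  expect_equal(median(en$zcr) * 400, 5, tolerance = 0.25)
  const <- matrix(0.5, 400, 3)
  expect_equal(rms_energy_zcr(const)$zcr, rep(0, 3))
})

test_that("MFCCs are deterministic, finite, and capture spectral tilt", {
  cl <- noise_clip(0.5, seed = 4)
  mag <- frame_spectra(frame_signal(cl, 0.025, 0.010)$frames)
  c1 <- mfcc(mag, 14, cfg)
  expect_equal(dim(c1)[1], 14)
  expect_identical(c1, mfcc(mag, 14, cfg))
  # low-passed noise has larger MFCC 1 than flat noise
  lp <- stats::filter(cl$samples, rep(1 / 8, 8), sides = 1)
  lp[is.na(lp)] <- 0
  maglp <- frame_spectra(frame_signal(audio_clip(as.numeric(lp), 16000),
                                      0.025, 0.010)$frames)
  expect_gt(mean(mfcc(maglp, 14, cfg)[1, ]), mean(c1[1, ]))
  sil <- frame_spectra(matrix(0, 400, 5))
  expect_true(all(is.finite(mfcc(sil, 14, cfg))))
})

test_that("spectral descriptors behave on tones, noise, and silence", {
  cl <- tone_clip(1000, dur = 0.5)
  fr <- frame_signal(cl, 0.025, 0.010)
  mag <- frame_spectra(fr$frames)
  spd <- spectral_descriptors(mag, fr$frames, cfg)
  bin_hz <- 16000 / 512
  expect_lt(max(abs(spd["centroid", ] - 1000)), bin_hz)
  # stationary signal: interior flux ~ 0
  expect_lt(max(spd["flux", -1]), 1e-6)
  expect_true(all(spd["harmonicity", ] > 0.8))

  nz <- noise_clip(0.5, seed = 5)
  frn <- frame_signal(nz, 0.025, 0.010)
  spn <- spectral_descriptors(frame_spectra(frn$frames), frn$frames, cfg)
  expect_gt(mean(spn["entropy", ]), mean(spd["entropy", ]))

  zero <- matrix(0, 257, 4)
  spz <- spectral_descriptors(zero, matrix(0, 400, 4), cfg)
  expect_true(all(spz[c("centroid", "rolloff_50", "slope", "entropy"), ] == 0))
  expect_true(all(is.finite(spz)))
})

test_that("rolloff points bracket the spectrum energy in order", {
  nz <- noise_clip(0.5, seed = 6)
  m <- extract_lld(nz, cfg)$values
  expect_true(all(m[, "rolloff_25"] <= m[, "rolloff_50"]))
  expect_true(all(m[, "rolloff_50"] <= m[, "rolloff_75"]))
  expect_true(all(m[, "rolloff_75"] <= m[, "rolloff_90"]))
})

test_that("SHS pitch tracking recovers a 220 Hz complex within 3%", {
  cl <- harmonic_clip(220, dur = 1)
  f0 <- f0_voicing(cl, cfg)
  med <- median(f0$f0[f0$f0 > 0])
  expect_lt(abs(med - 220) / 220, 0.03)
  expect_gt(mean(f0$voiced), 0.9)
  # amplitude invariance
  half <- audio_clip(cl$samples / 2, cl$rate)
  f0h <- f0_voicing(half, cfg)
  expect_equal(median(f0h$f0[f0h$f0 > 0]), med)
  # white noise is mostly unvoiced
  fn <- f0_voicing(noise_clip(1, seed = 7), cfg)
  expect_lt(mean(fn$voiced), 0.2)
})

test_that("viterbi smoothing matches the dynamic-programming reference", {
  for (s in 1:4) {
    sc <- with_seed(s, matrix(stats::runif(30 * 12), 30, 12))
    cand <- exp(seq(log(55), log(600), length.out = 30))
    expect_identical(as.integer(viterbi_path(sc, cand, 6)),
                     as.integer(viterbi_path_ref(sc, cand, 6)))
  }
})

test_that("jitter and shimmer measure cycle-level perturbation", {
  clean <- harmonic_clip(200, dur = 0.8)
  m <- extract_lld(clean, cfg)$values
  v <- m[, "f0"] > 0
  expect_lt(median(m[v, "jitter_local"]), 0.005)
  expect_lt(median(m[v, "shimmer_local"]), 0.005)

  pert <- harmonic_clip(200, dur = 0.8, period_jitter = 0.02, seed = 3,
                        id = "pert")
  mp <- extract_lld(pert, cfg)$values
  vp <- mp[, "f0"] > 0
  jit <- median(mp[vp, "jitter_local"])
  expect_gt(jit, 0.01)
  expect_lt(jit, 0.04)
  expect_true(all(mp[!vp, "jitter_local"] == 0))
})

test_that("HNR decreases monotonically with added noise", {
  base <- harmonic_clip(200, dur = 0.6)
  hnr_at <- function(noise_db) {
    nz <- with_seed(9, stats::rnorm(length(base$samples)))
    nz <- nz / sqrt(mean(nz^2)) * sqrt(mean(base$samples^2)) *
      10^(noise_db / 20)
    m <- extract_lld(audio_clip(base$samples + nz, 16000), cfg)$values
    median(m[m[, "f0"] > 0, "log_hnr"])
  }
  h20 <- hnr_at(-20)
  h10 <- hnr_at(-10)
  expect_gt(h20, h10)
  clean <- extract_lld(base, cfg)$values
  expect_gt(median(clean[clean[, "f0"] > 0, "log_hnr"]), 20)
})

test_that("the LLD matrix has the canonical 64 columns and group labels", {
  cl <- harmonic_clip(180, dur = 0.4)
  m <- extract_lld(cl, cfg)
  expect_equal(ncol(m$values), 64)
  expect_identical(colnames(m$values), lld_info()$name)
  expect_equal(unname(table(lld_info()$block)[c("energy", "spectral",
                                                "voicing")]),
               c(3L, 55L, 6L), ignore_attr = TRUE)
  expect_equal(sort(unique(lld_info()$group)),
               c("cepstral", "prosodic", "sound_quality", "spectral"))
  # determinism: bit-identical re-extraction
  expect_identical(m$values, extract_lld(cl, cfg)$values)
  expect_true(all(is.finite(m$values)))
})

test_that("gain scaling leaves scale-free descriptors unchanged", {
  cl <- harmonic_clip(150, dur = 0.5, amp = 0.8)
  half <- audio_clip(cl$samples * 0.5, cl$rate)
  m1 <- extract_lld(cl, cfg)$values
  m2 <- extract_lld(half, cfg)$values
  inv <- c("zcr", "centroid", "entropy", "rolloff_25", "rolloff_50",
           "rolloff_75", "rolloff_90", "f0", "jitter_local")
  for (col in inv) {
    expect_lt(max(abs(m1[, col] - m2[, col])) / (1 + max(abs(m1[, col]))),
              1e-6)
  }
  expect_true(all(m1[, "loudness"] >= m2[, "loudness"]))
  expect_equal(m1[, "rms_energy"], 2 * m2[, "rms_energy"], tolerance = 1e-9)
})

test_that("a one-hop shift moves contours by one frame", {
  cl <- harmonic_clip(170, dur = 0.5, amp = 0.6)
  hp <- round(cfg$hop * cfg$rate)
  shifted <- audio_clip(cl$samples[-seq_len(hp)], cl$rate)
  m1 <- extract_lld(cl, cfg)$values
  m2 <- extract_lld(shifted, cfg)$values
  n2 <- nrow(m2)
  interior <- 3:(n2 - 2)
  for (col in c("loudness", "rms_energy", "centroid", "entropy")) {
    expect_lt(max(abs(m1[interior + 1, col] - m2[interior, col])),
              1e-6 * (1 + max(abs(m1[, col]))))
  }
})

test_that("arbitrary finite input yields finite descriptors", {
  weird <- audio_clip(c(rep(0, 3000), stats::runif(3000, -1, 1),
                        rep(1, 1000), rep(-1, 1000)), 16000)
  m <- extract_lld(weird, cfg)
  expect_true(all(is.finite(m$values)))
  fv <- extract_features(m)
  expect_true(all(is.finite(fv)))
})
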