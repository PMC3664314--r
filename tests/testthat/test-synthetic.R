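small_cfg <- function(seed = 1, n = 6) {
  cfg <- synth_config(seed = seed)
  for (d in names(cfg$domains)) {
    cfg$domains[[d]]$n <- n
    cfg$domains[[d]]$duration <- c(2, 3)
  }
  cfg
}

test_that("clip synthesis responds to its acoustic drivers", {
  # slow modulation so the 60 ms analysis window sees a near-stationary
  # waveform when probing harmonicity
  base <- list(loud_db = -12, am_rate = 1, f0 = 220, noisiness = 0,
               shape = "flat")
  cl <- gen_clip(base, duration = 2, seed = 3)
  m <- extract_lld(cl)$values
  expect_gt(median(m[m[, "f0"] > 0, "log_hnr"]), 20)
  f0med <- median(m[m[, "f0"] > 0, "f0"])
  expect_lt(abs(f0med - 220) / 220, 0.03)

  # +6 dB loudness driver strictly raises extracted loudness
  louder <- gen_clip(modifyList(base, list(loud_db = -6)), 2, seed = 3)
  expect_gt(mean(extract_lld(louder)$values[, "loudness"]),
            mean(extract_lld(cl)$values[, "loudness"]))

  # 2 Hz amplitude modulation -> loudness-contour peaks 0.5 s apart.
  # F0 = 200 Hz keeps the analysis-window phase locked to the 10 ms hop
  # (exactly two cycles per hop), so the contour reflects the modulation
  # alone and not the window-phase ripple a non-commensurate fundamental
  # induces.
  am <- gen_clip(modifyList(base, list(am_rate = 2, f0 = 200)), 4, seed = 4)
  loud <- extract_lld(am)$values[, "loudness"]
  pk <- peaks_block(loud)
  expect_equal(unname(pk["peak_dist_mean"]) * 0.010, 0.5, tolerance = 0.03)
})

test_that("corpus generation is bit-reproducible and seed-sensitive", {
  cfg <- small_cfg(seed = 21, n = 4)
  c1 <- gen_corpus(cfg)
  c2 <- gen_corpus(cfg)
  expect_identical(c1$sound$clips[[1]]$samples, c2$sound$clips[[1]]$samples)
  expect_identical(c1$music$ratings$arousal$values,
                   c2$music$ratings$arousal$values)
  expect_identical(c1$sound$provenance, c2$sound$provenance)
  c3 <- gen_corpus(small_cfg(seed = 22, n = 4))
  expect_false(identical(c1$sound$clips[[1]]$samples,
                         c3$sound$clips[[1]]$samples))
})

test_that("the latent affect model follows the configured weights", {
  cfg <- small_cfg(seed = 8, n = 60)
  cfg$arousal <- list(weights = c(loudness = 1), noise_sd = 0)
  cfg$latent_sd <- 0.2       # keep the linear map clear of the [-1,1] clamp
  corpus <- gen_corpus(cfg)
  for (dom in corpus) {
    expect_equal(stats::cor(dom$latent_truth$arousal, dom$drivers$loud_db),
                 1, tolerance = 1e-9)
  }
  # valence weight on loudness flips sign in the music domain
  rv <- vapply(corpus, function(dom) {
    stats::cor(dom$latent_truth$valence, dom$drivers$loud_db)
  }, numeric(1))
  expect_lt(rv["sound"], 0)
  expect_gt(rv["music"], 0)
  expect_lt(rv["speech"], 0)
})

test_that("simulated raters discretize with the fixed thresholds", {
  truth <- data.frame(arousal = c(-0.9, -0.4, 0, 0.4, 0.9),
                      valence = rep(0, 5))
  rt <- simulate_raters(truth, list(K = 2, noise_sd = c(0, 0)),
                        "five_point", seed = 1)
  expect_equal(rt$arousal$values[, 1], c(-2, -1, 0, 1, 2),
               ignore_attr = TRUE)
  rtc <- simulate_raters(truth, list(K = 1, noise_sd = 0), "continuous",
                         seed = 1)
  expect_equal(rtc$arousal$values[, 1], truth$arousal, ignore_attr = TRUE)
})

test_that("feature-level domains carry the planted correlation structure", {
  doms <- gen_feature_level(n_domains = 3, n_per_domain = 500, d = 50,
                            s = 5, r_planted = 0.6, seed = 31)
  r <- feature_correlation(doms[[1]]$features, doms[[1]]$arousal)
  se <- 1 / sqrt(500)
  expect_true(all(abs(r[1:5] - 0.6) < 3 * se + 0.05))
  expect_lt(max(abs(r[11:50])), 4 * se)
  # s = d: selection recovers every planted feature
  all_planted <- gen_feature_level(n_domains = 2, n_per_domain = 200,
                                   d = 10, s = 5, r_planted = 0.7,
                                   seed = 32)
  tab <- relevance_table(all_planted, "arousal")
  top <- select_top_k(tab, "cdccJ", 5)
  expect_setequal(top, sprintf("planted_a_%03d", 1:5))
  # null configuration: no spuriously large pooled CDCC
  null <- gen_feature_level(n_domains = 3, n_per_domain = 200, d = 100,
                            s = 0, r_planted = 0, seed = 33)
  tn <- relevance_table(null, "arousal")
  expect_lt(max(abs(tn$cdccJ)), 0.25)
})

test_that("a written corpus directory round-trips through the loaders", {
  cfg <- small_cfg(seed = 41, n = 4)
  cfg$domains <- cfg$domains["sound"]
  corpus <- gen_corpus(cfg)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  wavs <- list.files(file.path(dir, "sound"), pattern = "\\.wav$")
  expect_equal(length(wavs), 4)
  cl <- load_clip(file.path(dir, "sound", wavs[1]), domain = "sound")
  expect_equal(cl$rate, 16000)
  orig <- corpus$sound$clips[[1]]$samples
  expect_lt(max(abs(cl$samples - orig)), 1e-4)   # 16-bit quantization
  rt <- read_ratings_csv(file.path(dir, "sound", "ratings.csv"),
                         scale = "five_point")
  expect_equal(dim(rt$arousal$values), c(4, 4))
})
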