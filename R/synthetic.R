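# Synthetic multi-domain corpora: audio clips with controlled acoustic
# drivers, latent arousal/valence as stated linear functions of the
# standardized drivers, and simulated raters of heterogeneous reliability.
# The generator carries the statistical structure the analysis assumes, so
# every pipeline stage can be exercised without the restricted corpora it
# emulates.

#' Configuration of the synthetic corpus generator
#'
#' Defaults encode the study conditions the package is validated under:
#' three domains of 200 instances each; short (2-4 s) sound and speech
#' clips and long (20-30 s) music-like clips; arousal driven by the
#' loudness level and the amplitude-modulation rate ("tempo"); valence
#' driven negatively by loudness and noisiness, with the loudness weight
#' sign-flipped in the music domain (mirroring the inverse meaning of
#' loudness for valence across domains); four raters per domain with
#' increasing noise, on a five-point scale for sound/music and a
#' continuous slider for speech.
#'
#' @param seed master seed; all randomness is derived from it.
#' @param domains per-domain settings: `n`, `duration` range (s), rating
#'   `scale`, and `shape_probs` over loudness-contour shapes
#'   (flat/ramp/parabola; music favours parabola).
#' @param drivers ranges of the acoustic drivers: `loud_db` (overall RMS
#'   level, dBFS), `am_rate` (Hz), `f0` (Hz, sampled log-uniformly),
#'   `noisiness` (noise energy fraction in \[0, 1\]).
#' @param arousal,valence affect model: `weights` over standardized
#'   drivers and the latent `noise_sd` (on the standardized scale).
#' @param valence_flip_domain domain whose valence loudness weight is
#'   sign-flipped (`NULL` for none).
#' @param latent_sd scale of the latent affect values on \[-1, 1\].
#' @param raters `K` raters with per-rater `noise_sd`.
#' @param rate synthesis sampling rate, Hz.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(
    seed = 1,
    domains = list(
      sound  = list(n = 200, duration = c(2, 4), scale = "five_point",
                    shape_probs = c(flat = 0.4, ramp = 0.3, parabola = 0.3)),
      music  = list(n = 200, duration = c(20, 30), scale = "five_point",
                    shape_probs = c(flat = 0.2, ramp = 0.2, parabola = 0.6)),
      speech = list(n = 200, duration = c(2, 4), scale = "continuous",
                    shape_probs = c(flat = 0.4, ramp = 0.3, parabola = 0.3))),
    drivers = list(loud_db = c(-25, -5), am_rate = c(1, 6),
                   f0 = c(90, 350), noisiness = c(0.05, 0.8)),
    arousal = list(weights = c(loudness = 0.6, tempo = 0.35),
                   noise_sd = 0.25),
    valence = list(weights = c(loudness = -0.45, noisiness = -0.3),
                   noise_sd = 0.3),
    valence_flip_domain = "music",
    latent_sd = 0.45,
    raters = list(K = 4, noise_sd = c(0.10, 0.20, 0.30, 0.45)),
    rate = 16000) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  need <- c("seed", "domains", "drivers", "arousal", "valence",
            "latent_sd", "raters", "rate")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop("synth_config missing field(s): ", paste(miss, collapse = ", "))
  }
  for (d in names(cfg$domains)) {
    dom <- cfg$domains[[d]]
    for (f in c("n", "duration", "scale", "shape_probs")) {
      if (is.null(dom[[f]])) stop("domain '", d, "' missing field: ", f)
    }
    if (dom$n < 4) stop("domain '", d, "': n must be >= 4")
  }
  if (any(!is.finite(unlist(cfg$arousal$weights))) ||
      any(!is.finite(unlist(cfg$valence$weights)))) {
    stop("affect weights must be finite")
  }
  if (cfg$arousal$noise_sd < 0 || cfg$valence$noise_sd < 0 ||
      any(cfg$raters$noise_sd < 0)) {
    stop("noise SDs must be >= 0")
  }
  if (length(cfg$raters$noise_sd) != cfg$raters$K) {
    stop("raters: need one noise_sd per rater (K)")
  }
  invisible(cfg)
}

#' Synthesize one audio clip from acoustic drivers
#'
#' A harmonic complex at the requested F0 (eight 1/h-weighted partials
#' with random phases) is mixed with white noise at the requested energy
#' fraction, amplitude-modulated at the "tempo" rate (depth 0.4), shaped
#' by the chosen loudness contour, and scaled to the requested overall RMS
#' level.
#'
#' @param drivers list/row with `loud_db`, `am_rate`, `f0`, `noisiness`,
#'   `shape` (one of `"flat"`, `"ramp"`, `"parabola"`).
#' @param duration clip length in seconds.
#' @param rate sampling rate, Hz.
#' @param seed integer seed.
#' @param clip_id,domain clip metadata.
#' @return an [audio_clip()].
#' @export
gen_clip <- function(drivers, duration, rate = 16000, seed = 1,
                     clip_id = "synth", domain = "synthetic") {
  stopifnot(drivers$noisiness >= 0, drivers$noisiness <= 1,
            drivers$f0 > 0, duration > 0)
  with_seed(seed, {
    n <- round(duration * rate)
    tt <- (seq_len(n) - 1) / rate
    ph <- stats::runif(8, 0, 2 * pi)
    harm <- 0
    for (h in 1:8) harm <- harm + sin(2 * pi * h * drivers$f0 * tt + ph[h]) / h
    harm <- harm / sqrt(mean(harm^2))
    nu <- drivers$noisiness
    sig <- sqrt(1 - nu) * harm
    if (nu > 0) {
      nz <- stats::rnorm(n)
      sig <- sig + sqrt(nu) * nz / sqrt(mean(nz^2))
    }
    env <- switch(drivers$shape,
                  flat = rep(1, n),
                  ramp = 0.3 + 0.7 * tt / duration,
                  parabola = 0.25 + 0.75 *
                    (1 - ((tt - duration / 2) / (duration / 2))^2),
                  stop("unknown contour shape: ", drivers$shape))
    am <- (1 + 0.4 * sin(2 * pi * drivers$am_rate * tt - pi / 2)) / 1.4
    x <- sig * env * am
    x <- x / sqrt(mean(x^2)) * 10^(drivers$loud_db / 20)
    peak <- max(abs(x))
    if (peak > 0.99) x <- x * 0.99 / peak
    audio_clip(x, rate, clip_id, domain)
  })
}

zstd <- function(x) {
  s <- safe_sd(x)
  if (s < EPS) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a full synthetic multi-domain corpus
#'
#' Samples acoustic drivers per domain, synthesizes the clips, derives the
#' latent arousal/valence as the configured linear functions of the
#' standardized drivers plus Gaussian noise (rescaled to `latent_sd` and
#' clipped to \[-1, 1\]), and simulates the raters.  Bit-identical for a
#' fixed configuration.
#'
#' @param config a [synth_config()].
#' @return named list (one element per domain) of `synth_corpus` objects:
#'   `clips`, `drivers`, `latent_truth` (never fed to the pipeline),
#'   `ratings` (arousal/valence [rating_matrix()]), `provenance`.
#' @export
gen_corpus <- function(config = synth_config()) {
  validate_synth_config(config)
  hash <- config_hash(unclass(config))
  out <- list()
  for (di in seq_along(config$domains)) {
    dname <- names(config$domains)[di]
    dom <- config$domains[[di]]
    dseed <- derive_seed(config$seed, di * 1000)
    drv <- with_seed(dseed, {
      data.frame(
        loud_db = stats::runif(dom$n, config$drivers$loud_db[1],
                               config$drivers$loud_db[2]),
        am_rate = stats::runif(dom$n, config$drivers$am_rate[1],
                               config$drivers$am_rate[2]),
        f0 = exp(stats::runif(dom$n, log(config$drivers$f0[1]),
                              log(config$drivers$f0[2]))),
        noisiness = stats::runif(dom$n, config$drivers$noisiness[1],
                                 config$drivers$noisiness[2]),
        shape = sample(names(dom$shape_probs), dom$n, replace = TRUE,
                       prob = dom$shape_probs),
        duration = stats::runif(dom$n, dom$duration[1], dom$duration[2]),
        stringsAsFactors = FALSE)
    })
    z <- list(loudness = zstd(drv$loud_db), tempo = zstd(drv$am_rate),
              f0 = zstd(log(drv$f0)), noisiness = zstd(drv$noisiness))
    latent <- function(model, flip_loudness = FALSE) {
      w <- model$weights
      if (flip_loudness && "loudness" %in% names(w)) {
        w["loudness"] <- -w["loudness"]
      }
      raw <- rep(0, dom$n)
      for (nm in names(w)) raw <- raw + w[[nm]] * z[[nm]]
      raw <- raw + with_seed(derive_seed(dseed, 1),
                             stats::rnorm(dom$n, 0, model$noise_sd))
      sd_nom <- sqrt(sum(w^2) + model$noise_sd^2)
      clamp(raw / sd_nom * config$latent_sd, -1, 1)
    }
    truth <- data.frame(
      arousal = latent(config$arousal),
      valence = latent(config$valence,
                       flip_loudness = identical(dname,
                                                 config$valence_flip_domain)))
    ratings <- simulate_raters(truth, config$raters, dom$scale,
                               derive_seed(dseed, 2))
    clips <- lapply(seq_len(dom$n), function(i) {
      gen_clip(drv[i, ], drv$duration[i], config$rate,
               seed = derive_seed(dseed, 10 + i),
               clip_id = sprintf("%s_%03d", dname, i),
               domain = if (dname %in% c("sound", "music")) dname
                        else "synthetic")
    })
    out[[dname]] <- structure(
      list(domain = dname, clips = clips, drivers = drv,
           latent_truth = truth, ratings = ratings, provenance = hash),
      class = "synth_corpus")
  }
  out
}

simulate_raters <- function(truth, raters, scale, seed) {
  one_dim <- function(latent, dim_offset) {
    v <- with_seed(derive_seed(seed, dim_offset), {
      sapply(seq_len(raters$K), function(k) {
        y <- latent + stats::rnorm(length(latent), 0, raters$noise_sd[k])
        if (scale == "five_point") {
          as.numeric(cut(y, c(-Inf, -0.6, -0.2, 0.2, 0.6, Inf))) - 3
        } else {
          clamp(y, -1, 1)
        }
      })
    })
    rating_matrix(v, scale)
  }
  list(arousal = one_dim(truth$arousal, 1), valence = one_dim(truth$valence, 2))
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf("<synth_corpus '%s': %d clips, %d raters, provenance %s>\n",
              x$domain, length(x$clips),
              length(x$ratings$arousal$rater_ids),
              substr(x$provenance, 1, 8)))
  invisible(x)
}

#' Feature-level synthetic domains (no audio)
#'
#' Draws feature matrices directly: `s` planted features share a latent
#' factor with the target in every domain (population correlation
#' `r_planted`; the valence-planted block flips sign in
#' `flip_domain`), the rest are independent noise.  Fast, analytically
#' controllable statistics for testing selection and regression.
#'
#' @param n_domains,n_per_domain,d,s problem sizes: domains, instances per
#'   domain, total features, planted features per affect dimension.
#' @param r_planted population correlation of planted features with their
#'   latent factor.
#' @param flip_domain index/name of the domain whose valence-planted block
#'   is sign-flipped (`NULL` for none).
#' @param seed master seed.
#' @return named list of domain datasets (`features`, `arousal`,
#'   `valence`), suitable for [relevance_table()] and
#'   [cross_domain_grid()].
#' @export
gen_feature_level <- function(n_domains = 3, n_per_domain = 200, d = 500,
                              s = 20, r_planted = 0.6, flip_domain = NULL,
                              seed = 1) {
  stopifnot(2 * s <= d, r_planted >= 0, r_planted <= 1)
  doms <- paste0("domain_", seq_len(n_domains))
  feats <- c(sprintf("planted_a_%03d", seq_len(s)),
             sprintf("planted_v_%03d", seq_len(s)),
             sprintf("noise_%04d", seq_len(d - 2 * s)))
  out <- list()
  for (di in seq_len(n_domains)) {
    out[[doms[di]]] <- with_seed(derive_seed(seed, di), {
      n <- n_per_domain
      g <- stats::rnorm(n)   # arousal factor
      h <- stats::rnorm(n)   # valence factor
      flip <- if (!is.null(flip_domain) &&
                  (isTRUE(flip_domain == di) ||
                   identical(as.character(flip_domain), doms[di]))) -1 else 1
      planted <- function(fac, sgn) {
        matrix(vapply(seq_len(s), function(j) {
          sgn * r_planted * fac +
            sqrt(1 - r_planted^2) * stats::rnorm(n)
        }, numeric(n)), nrow = n)
      }
      f <- cbind(planted(g, 1), planted(h, flip),
                 matrix(stats::rnorm(n * (d - 2 * s)), n))
      colnames(f) <- feats
      list(features = f, arousal = g, valence = h)
    })
  }
  out
}

#' Write a synthetic corpus to a directory
#'
#' WAV files, long-format ratings CSV, latent-truth CSV (kept separate
#' from everything the pipeline consumes) and a JSON manifest with the
#' configuration hash.
#'
#' @param corpus output of [gen_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dom in corpus) {
    ddir <- file.path(dir, dom$domain)
    dir.create(ddir, showWarnings = FALSE)
    for (cl in dom$clips) {
      write_wav(cl$samples, cl$rate, file.path(ddir, paste0(cl$clip_id,
                                                            ".wav")))
    }
    ids <- vapply(dom$clips, function(cl) cl$clip_id, "")
    long <- do.call(rbind, lapply(seq_along(dom$ratings$arousal$rater_ids),
      function(k) data.frame(
        instance_id = ids,
        rater_id = dom$ratings$arousal$rater_ids[k],
        arousal = dom$ratings$arousal$values[, k],
        valence = dom$ratings$valence$values[, k])))
    utils::write.csv(long, file.path(ddir, "ratings.csv"), row.names = FALSE)
    utils::write.csv(cbind(instance_id = ids, dom$latent_truth),
                     file.path(ddir, "truth.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(domains = names(corpus),
         provenance = corpus[[1]]$provenance,
         n = vapply(corpus, function(d) length(d$clips), 0L)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
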