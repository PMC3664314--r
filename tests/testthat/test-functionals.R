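test_that("the regression delta is linear with replicated edges", {
  expect_equal(delta_contour(rep(3, 10)), rep(0, 10))
  ramp <- 0.5 * (1:20)
  d <- delta_contour(ramp)
  expect_equal(d[3:18], rep(0.5, 16))
  x <- with_seed(1, stats::rnorm(50))
  expect_equal(delta_contour(-x), -delta_contour(x))
  expect_equal(delta_contour(5), 0)
})

test_that("percentile functionals use the interpolating estimator", {
  p <- percentiles_block(1:100)
  expect_equal(unname(p["quartile_2"]), 50.5)
  expect_equal(unname(p["iqr_1_3"]),
               unname(p["quartile_3"] - p["quartile_1"]))
  pc <- percentiles_block(rep(2.5, 30))
  expect_true(all(pc[c("quartile_1", "quartile_2", "quartile_3")] == 2.5))
  expect_true(all(pc[c("iqr_1_2", "iqr_2_3", "iqr_1_3", "range_1_99")] == 0))
})

test_that("moment functionals match hand arithmetic and conventions", {
  m <- moments_block(c(-1, 1))
  expect_equal(unname(m["amean"]), 0)
  expect_equal(unname(m["rqmean"]), 1)
  m2 <- moments_block(c(0, 0, 0, 3))
  expect_equal(unname(m2["amean"]), 0.75)
  expect_equal(unname(m2["rqmean"]), 1.5)
  sym <- c(-3, -1, 0, 1, 3)
  expect_lt(abs(moments_block(sym)["skewness"]), 1e-12)
  mc <- moments_block(rep(7, 9))
  expect_true(all(mc[c("stddev", "skewness", "kurtosis")] == 0))
})

test_that("temporal functionals count durations and segments", {
  tb <- temporal_block(1:10)
  expect_equal(unname(tb["rise_duration"]), 1)
  expect_equal(unname(tb["pos_max"]), 1)
  tc <- temporal_block(rep(4, 6))
  expect_equal(unname(tc["pct_nonzero"]), 1)
  expect_equal(unname(tc["range"]), 0)
  ts <- temporal_block(c(0, 1, 0, 1, 0))
  expect_equal(unname(ts["seglen_mean"]), 1)
  expect_equal(unname(ts["seglen_max"]), 1)
  # two runs above the 25%-range threshold
  expect_equal(unname(ts["seglen_sd"]), 0)
  expect_equal(unname(ts["up50_duration"]), 2 / 5)
})

test_that("peak functionals recover the period of a sinusoidal contour", {
  P <- 20
  x <- sin(2 * pi * (0:(6 * P)) / P)
  pk <- peaks_block(x)
  expect_equal(unname(pk["peak_dist_mean"]), P, tolerance = 1 / P)
  expect_lt(unname(pk["peak_dist_sd"]), 0.51)
  mono <- peaks_block(seq(0, 1, length.out = 40))
  expect_true(all(mono == 0))
  xj <- with_seed(4, {
    jumps <- round(P * (1 + stats::runif(12, -0.25, 0.25)))
    unlist(lapply(jumps, function(p) sin(2 * pi * (0:(p - 1)) / p)))
  })
  expect_gt(peaks_block(xj)["peak_dist_sd"], 1)
})

test_that("regression functionals fit lines and parabolas exactly", {
  n <- 21
  tt <- (0:(n - 1)) / (n - 1)
  r <- regression_block(2 * tt + 1)
  expect_equal(unname(r["linreg_slope"]), 2, tolerance = 1e-10)
  expect_equal(unname(r["linreg_offset"]), 1, tolerance = 1e-10)
  expect_lt(unname(r["linreg_err"]), 1e-20)
  par <- 4 * (tt - 0.5)^2 + 0.3
  rp <- regression_block(par)
  expect_lt(abs(rp["linreg_slope"]), 1e-10)
  expect_lt(unname(rp["quadreg_err"]), 1e-20)
  expect_equal(unname(rp["quadreg_a"]), 4, tolerance = 1e-8)
  # quadratic offset equals the fitted value at contour start
  expect_equal(unname(rp["quadreg_offset"]), par[1], tolerance = 1e-8)
})

test_that("linear prediction separates noise from periodic contours", {
  x <- with_seed(11, stats::rnorm(4000))
  mb <- modulation_block(x)
  expect_lt(max(abs(mb[paste0("lp_coef_", 1:5)])), 0.1)
  expect_equal(unname(mb["lp_gain"]), stats::var(x) * (length(x) - 1) /
                 length(x), tolerance = 0.1)
  per <- sin(2 * pi * (0:999) / 25)
  mp <- modulation_block(per)
  expect_lt(unname(mp["lp_gain"]), 0.01 * mean(per^2))
  expect_identical(modulation_block(per), mp)
  expect_true(all(modulation_block(c(1, 2, 3)) == 0))
})

test_that("the compiled bank matches the reference blocks column by column", {
  set.seed(20)
  for (n in c(1, 2, 3, 4, 6, 7, 30, 500)) {
    M <- cbind(stats::rnorm(n), cumsum(stats::rnorm(n)), rep(1, n),
               c(rep(0, n %/% 2), rep(3, n - n %/% 2)),
               sin(2 * pi * (1:n) / 12), abs(stats::rnorm(n)))
    colnames(M) <- paste0("c", 1:6)
    B <- functional_bank_matrix(M)
    for (k in seq_len(ncol(M))) {
      ref <- compute_all_functionals(unname(M[, k]))
      expect_lt(max(abs(B[k, names(ref)] - ref)), 1e-8)
    }
  }
})

test_that("a constant contour forces the analytic values in every family", {
  f <- compute_all_functionals(rep(2, 40))
  expect_equal(unname(f["amean"]), 2)
  expect_equal(unname(f["quartile_2"]), 2)
  expect_lt(max(abs(f[c("stddev", "range", "linreg_slope", "quadreg_a",
                        "peak_mean", "peak_dist_mean", "lp_gain",
                        "seglen_mean")])), 1e-9)
  expect_equal(unname(f["pct_nonzero"]), 1)
})

test_that("the feature index enumerates exactly 6373 traceable dimensions", {
  idx <- feature_index()
  expect_equal(nrow(idx), 6373)
  expect_false(any(duplicated(idx$name)))
  expect_setequal(unique(idx$functional_family),
                  c("percentiles", "temporal", "moments", "modulation",
                    "peaks", "regression"))
  expect_setequal(unique(idx$lld_name), lld_info()$name)
  # composition rules of the manifest
  expect_equal(sum(idx$functional_name == "pct_nonzero"), 1)
  expect_true(all(!idx$is_delta[startsWith(idx$functional_name, "seglen")]))
  expect_equal(sum(idx$is_delta & idx$functional_family == "modulation" &
                     startsWith(idx$lld_name, "rasta_band_")), 0)
  fi <- functional_info()
  expect_equal(nrow(fi), 54)
  expect_equal(sum(fi$applies_to == "lld_and_delta"), 35)
})

test_that("extracted features are traceable to their contour statistics", {
  cl <- harmonic_clip(200, dur = 0.4)
  m <- extract_lld(cl)
  fv <- extract_features(m)
  expect_equal(length(fv), 6373)
  expect_equal(unname(fv["loudness__amean"]), mean(m$values[, "loudness"]))
  expect_equal(unname(fv["f0__pct_nonzero"]), mean(m$values[, "f0"] != 0))
  expect_equal(unname(fv["centroid_de__amean"]),
               mean(delta_contour(m$values[, "centroid"])))
  expect_identical(fv, extract_features(m))
})

test_that("non-finite cells abort with the offending dimension named", {
  cl <- tone_clip(250, dur = 0.3)
  m <- extract_lld(cl)
  m$values[3, "centroid"] <- NaN
  expect_error(extract_features(m), "centroid")
})
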