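test_that("scale mapping sends the five-point scale onto [-1, 1]", {
  m <- rating_matrix(matrix(c(2, -2, 0, 1, -1, 2), 3, 2),
                     scale = "five_point")
  mapped <- map_scale(m)
  expect_equal(mapped$values[, 1], c(1, -1, 0), ignore_attr = TRUE)
  expect_equal(mapped$values[, 2], c(0.5, -0.5, 1), ignore_attr = TRUE)
  cont <- rating_matrix(matrix(0.37, 1, 1), scale = "continuous")
  expect_equal(map_scale(cont)$values[1, 1], 0.37, ignore_attr = TRUE)
  expect_error(rating_matrix(matrix(c(2, 1.5), 1, 2), scale = "five_point"),
               "out of declared")
  expect_error(rating_matrix(matrix(1.2, 1, 1), scale = "continuous"),
               "out of declared")
})

test_that("rater confidence ranks raters by their noise level", {
  expect_equal(
    unname(rater_confidence(rating_matrix(matrix(c(1, 0, -1), 3, 4) / 2))),
    rep(1, 4))
  # exact negation: the mean column is constant -> confidence 0 by
  # convention (one warning per degenerate rater)
  y <- c(-0.5, 0, 0.5)
  neg <- rating_matrix(cbind(y, -y))
  expect_warning(expect_warning(r <- rater_confidence(neg), "degenerate"),
                 "degenerate")
  expect_equal(unname(r), c(0, 0))
  # heterogeneous noise: r_1 > r_2 > r_3 for SDs 0.1 < 0.3 < 0.6
  ok <- vapply(1:10, function(s) {
    truth <- with_seed(s, stats::runif(80, -1, 1))
    v <- with_seed(s + 100, sapply(c(0.1, 0.3, 0.6), function(sd) {
      pmin(1, pmax(-1, truth + stats::rnorm(80, 0, sd)))
    }))
    r <- rater_confidence(rating_matrix(v))
    r[1] > r[2] && r[2] > r[3]
  }, logical(1))
  expect_gt(mean(ok), 0.8)
})

test_that("EWE is the confidence-weighted mean with clamped weights", {
  one <- rating_matrix(matrix(c(0.2, -0.4), 2, 1))
  expect_equal(ewe(one)$ewe, c(0.2, -0.4))
  # hand example: r = (0.8, 0.4), y = (1.0, 0.4) -> 0.8 exactly
  g <- ewe(rating_matrix(matrix(c(1.0, 0.4), 1, 2)),
           confidence = c(0.8, 0.4))
  expect_equal(unname(g$ewe), 0.8)
  # equal confidences reduce to the plain mean
  v <- with_seed(3, matrix(stats::runif(40, -1, 1), 10, 4))
  geq <- ewe(rating_matrix(v), confidence = rep(0.7, 4))
  expect_equal(geq$ewe, rowMeans(v), tolerance = 1e-12)
  # negative confidences are unusable
  expect_error(ewe(rating_matrix(v), confidence = c(-0.2, -0.1, 0, -1)),
               "confidences")
  # missing ratings: rater dropped instance-wise with renormalization
  v2 <- v
  v2[1, 2:4] <- NA
  gm <- ewe(rating_matrix(v2), confidence = c(0.5, 0.5, 0.5, 0.5))
  expect_equal(gm$ewe[1], v[1, 1])
  expect_equal(gm$ewe[-1], rowMeans(v)[-1], tolerance = 1e-12)
})

test_that("EWE tracks the latent truth at least as well as the best rater", {
  # comparable raters (no single dominant annotator): the regime the
  # confidence-weighted fusion is designed for
  worse <- 0
  for (s in 1:20) {
    truth <- with_seed(s, stats::runif(100, -1, 1))
    v <- with_seed(1000 + s, sapply(c(0.25, 0.35, 0.45, 0.6), function(sd) {
      pmin(1, pmax(-1, truth + stats::rnorm(100, 0, sd)))
    }))
    g <- ewe(rating_matrix(v))
    best <- max(apply(v, 2, stats::cor, y = truth))
    if (stats::cor(g$ewe, truth) < best - 0.02) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("2-d binning covers [-1,1]^2 with right-closed equal bins", {
  b <- bin_2d(rep(0, 7), rep(0, 7))
  expect_equal(b[3, 3], 7L)
  expect_equal(sum(b), 7L)
  centers <- seq(-0.8, 0.8, by = 0.4)
  grid <- expand.grid(a = centers, v = centers)
  expect_true(all(bin_2d(grid$a, grid$v) == 1L))
  expect_equal(bin_2d(1, 1)[5, 5], 1L)       # +1 falls in the top bin
  expect_equal(bin_2d(-1, -1)[1, 1], 1L)     # -1 included in the lowest
  expect_equal(bin_2d(-0.2, 0)[2, 3], 1L)    # interior edges right-closed
})

test_that("gold standard fusion exposes a rank-correlation between axes", {
  truth_a <- with_seed(5, stats::runif(60, -1, 1))
  truth_v <- pmin(1, pmax(-1, 0.6 * truth_a +
                            with_seed(6, stats::rnorm(60, 0, 0.3))))
  mk <- function(truth, s) {
    rating_matrix(with_seed(s, sapply(1:4, function(k) {
      pmin(1, pmax(-1, truth + stats::rnorm(60, 0, 0.2)))
    })))
  }
  gs <- gold_standard(list(arousal = mk(truth_a, 7), valence = mk(truth_v, 8),
                           instance_ids = sprintf("i%02d", 1:60)))
  rho <- stats::cor(gs$gold$arousal, gs$gold$valence, method = "spearman")
  # rank-based oracle: pearson on ranks
  oracle <- stats::cor(rank(gs$gold$arousal), rank(gs$gold$valence))
  expect_equal(rho, oracle, tolerance = 1e-12)
  expect_gt(rho, 0.3)
})

test_that("ratings CSV round-trips through the long format", {
  df <- data.frame(instance_id = rep(c("a", "b", "c"), each = 2),
                   rater_id = rep(c("r1", "r2"), 3),
                   arousal = c(1, 2, 0, -1, 2, 2),
                   valence = c(-2, -1, 0, 0, 1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  r <- read_ratings_csv(f, scale = "five_point")
  expect_equal(r$instance_ids, c("a", "b", "c"))
  expect_equal(unname(r$arousal$values["b", "r2"]), -1)
  expect_error(read_ratings_csv({
    f2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(df[, -3], f2, row.names = FALSE)
    f2
  }), "missing column")
})
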