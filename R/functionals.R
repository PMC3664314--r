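# The functional bank: statistics mapping an LLD contour (or its delta)
# to one number each.  Six families: percentiles, moments, temporal,
# modulation, peaks, regression.

pop_sd <- function(x) if (length(x) == 0) 0 else sqrt(mean((x - mean(x))^2))

#' First-order regression delta of a contour
#'
#' Regression-style slope estimate with a two-frame symmetric context and
#' edge replication, so the output has the length of the input.  A linear
#' ramp of slope m per frame maps to a constant m; a length-1 contour maps
#' to 0.
#'
#' @param x numeric contour.
#' @return numeric vector, same length as `x`.
#' @export
delta_contour <- function(x) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  xp <- c(x[1], x[1], x, x[n], x[n])
  t <- seq_len(n) + 2
  ((xp[t + 1] - xp[t - 1]) + 2 * (xp[t + 2] - xp[t - 2])) / 10
}

#' Percentile functionals of a contour
#'
#' Quartiles, the three inter-quartile ranges, the 1% and 99% percentiles
#' and their range, all with the linear-interpolation percentile estimator.
#'
#' @param x numeric contour (non-empty).
#' @return named numeric vector of 9 functionals.
#' @export
percentiles_block <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75, 0.01, 0.99), names = FALSE,
                       type = 7)
  c(quartile_1 = q[1], quartile_2 = q[2], quartile_3 = q[3],
    iqr_1_2 = q[2] - q[1], iqr_2_3 = q[3] - q[2], iqr_1_3 = q[3] - q[1],
    percentile_1 = q[4], percentile_99 = q[5], range_1_99 = q[5] - q[4])
}

#' Moment functionals of a contour
#'
#' Arithmetic mean, root quadratic mean, (population) standard deviation,
#' and standardized skewness and excess kurtosis; the latter two are 0 by
#' convention for (near-)constant contours.
#'
#' @param x numeric contour (non-empty).
#' @return named numeric vector of 5 functionals.
#' @export
moments_block <- function(x) {
  m <- mean(x)
  d <- x - m
  s2 <- mean(d^2)
  c(amean = m, rqmean = sqrt(mean(x^2)), stddev = sqrt(s2),
    skewness = if (s2 > EPS) mean(d^3) / s2^1.5 else 0,
    kurtosis = if (s2 > EPS) mean(d^4) / s2^2 - 3 else 0)
}

#' Temporal functionals of a contour
#'
#' Normalized positions of the extrema, range, contour centroid (first
#' moment of the non-negatively shifted contour over normalized time),
#' flatness (geometric over arithmetic mean of magnitudes), relative
#' durations above 25/50/75/90% of the range, relative duration rising and
#' with positive curvature, segment-length statistics (maximal runs above
#' min + 0.25 range, in frames) and the percentage of non-zero frames.
#'
#' @param x numeric contour (non-empty).
#' @return named numeric vector of 16 functionals.
#' @export
temporal_block <- function(x) {
  n <- length(x)
  den <- max(n - 1, 1)
  tt <- (seq_len(n) - 1) / den
  mn <- min(x); mx <- max(x); rg <- mx - mn
  shifted <- x - mn
  centroid <- if (sum(shifted) > EPS) sum(tt * shifted) / sum(shifted) else 0.5
  ax <- abs(x)
  flat <- exp(mean(log(ax + EPS))) / (mean(ax) + EPS)
  updur <- function(q) mean(x > mn + q * rg)
  rise <- if (n >= 2) mean(diff(x) > 0) else 0
  curv <- if (n >= 3) mean(diff(x, differences = 2) > 0) else 0

  seg <- c(seglen_mean = 0, seglen_max = 0, seglen_min = 0, seglen_sd = 0)
  if (rg > EPS) {
    r <- rle(x > mn + 0.25 * rg)
    lens <- r$lengths[r$values]
    if (length(lens) > 0) {
      seg <- c(seglen_mean = mean(lens), seglen_max = max(lens),
               seglen_min = min(lens), seglen_sd = pop_sd(lens))
    }
  }
  c(pos_min = (unname(which.min(x)) - 1) / den,
    pos_max = (unname(which.max(x)) - 1) / den,
    range = rg, contour_centroid = centroid, flatness = flat,
    up25_duration = updur(0.25), up50_duration = updur(0.50),
    up75_duration = updur(0.75), up90_duration = updur(0.90),
    rise_duration = rise, curvature_duration = curv,
    seg, pct_nonzero = mean(ax > EPS))
}

find_peaks <- function(x, gate_mean = TRUE) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  p <- i[x[i] > x[i - 1] & x[i] > x[i + 1]]
  if (gate_mean) p[x[p] > mean(x)] else p
}

find_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] < x[i - 1] & x[i] < x[i + 1]]
}

# fraction of the contour range a local maximum must rise above its
# flanking minima to count as a peak (guards the peak statistics against
# numerical ripple on otherwise smooth contours)
PEAK_SALIENCE <- 0.05

#' Peak functionals of a contour
#'
#' A peak is a strict local maximum that exceeds the contour mean and
#' rises at least 5% of the contour range above the higher of its two
#' flanking local minima (contour ends count as minima), so that
#' negligible ripple on a smooth contour is not counted.  Reports mean
#' peak value (absolute and relative to the mean), mean and SD of the
#' inter-peak distances (frames), parabolic-refined amplitude statistics
#' of peaks and of local minima, and mean/SD of the rising and falling
#' slopes flanking each peak (units per frame, anchored at the flanking
#' minima).  A contour without peaks yields all zeros.
#'
#' @param x numeric contour (non-empty).
#' @return named numeric vector of 11 functionals.
#' @export
peaks_block <- function(x) {
  out <- c(peak_mean = 0, peak_mean_rel = 0, peak_dist_mean = 0,
           peak_dist_sd = 0, peak_amp_mean = 0, min_amp_mean = 0,
           peak_amp_range = 0, rise_slope_mean = 0, rise_slope_sd = 0,
           fall_slope_mean = 0, fall_slope_sd = 0)
  pk <- find_peaks(x)
  if (length(pk) == 0) return(out)
  mins <- find_minima(x)
  anchors <- sort(unique(c(1L, mins, length(x))))
  fi <- findInterval(pk, anchors)   # peaks are never anchors
  prev <- anchors[fi]
  nxt <- anchors[fi + 1]
  keep <- x[pk] - pmax(x[prev], x[nxt]) >=
    PEAK_SALIENCE * (max(x) - min(x))
  pk <- pk[keep]; prev <- prev[keep]; nxt <- nxt[keep]
  if (length(pk) == 0) return(out)
  # parabolic amplitude refinement, vectorized over peaks
  y1 <- x[pk - 1]; y2 <- x[pk]; y3 <- x[pk + 1]
  den <- y1 - 2 * y2 + y3
  d <- ifelse(abs(den) < EPS, 0, clamp(0.5 * (y1 - y3) / den, -1, 1))
  amp <- y2 - 0.25 * (y1 - y3) * d
  out["peak_mean"] <- mean(y2)
  out["peak_mean_rel"] <- mean(y2) - mean(x)
  if (length(pk) >= 2) {
    dd <- diff(pk)
    out["peak_dist_mean"] <- mean(dd)
    out["peak_dist_sd"] <- pop_sd(dd)
  }
  out["peak_amp_mean"] <- mean(amp)
  if (length(mins) > 0) out["min_amp_mean"] <- mean(x[mins])
  out["peak_amp_range"] <- max(amp) - min(amp)
  rises <- (y2 - x[prev]) / (pk - prev)
  falls <- (y2 - x[nxt]) / (nxt - pk)
  out["rise_slope_mean"] <- mean(rises)
  out["rise_slope_sd"] <- pop_sd(rises)
  out["fall_slope_mean"] <- mean(falls)
  out["fall_slope_sd"] <- pop_sd(falls)
  out
}

#' Regression functionals of a contour
#'
#' Least-squares linear and quadratic fits over time normalized to
#' \[0, 1\], so offsets (fitted value at t = 0) are duration invariant.
#' Errors are mean squared residuals.  Contours too short for a fit yield
#' zeros for that fit.
#'
#' @param x numeric contour (non-empty).
#' @return named numeric vector of 7 functionals.
#' @export
regression_block <- function(x) {
  n <- length(x)
  out <- c(linreg_slope = 0, linreg_offset = 0, linreg_err = 0,
           quadreg_a = 0, quadreg_b = 0, quadreg_offset = 0, quadreg_err = 0)
  if (n >= 2) {
    tt <- (seq_len(n) - 1) / (n - 1)
    vt <- sum((tt - mean(tt))^2)
    sl <- sum((tt - mean(tt)) * (x - mean(x))) / vt
    off <- mean(x) - sl * mean(tt)
    out["linreg_slope"] <- sl
    out["linreg_offset"] <- off
    out["linreg_err"] <- mean((x - off - sl * tt)^2)
    if (n >= 3) {
      X <- cbind(tt^2, tt, 1)
      cf <- tryCatch(qr.solve(X, x), error = function(e) c(0, 0, 0))
      out["quadreg_a"] <- cf[1]
      out["quadreg_b"] <- cf[2]
      out["quadreg_offset"] <- cf[3]
      out["quadreg_err"] <- mean((x - X %*% cf)^2)
    }
  }
  out
}

#' Modulation (linear prediction) functionals of a contour
#'
#' Order-5 linear prediction by the autocorrelation method on the
#' mean-removed contour.  Coefficients follow the predictor convention
#' x_t = sum_k a_k x_(t-k); gain is the residual (prediction error)
#' energy.  Contours of length 5 or less, or without variance, yield
#' zeros.
#'
#' @param x numeric contour.
#' @return named numeric vector of 6 functionals.
#' @export
modulation_block <- function(x) {
  out <- c(lp_gain = 0, lp_coef_1 = 0, lp_coef_2 = 0, lp_coef_3 = 0,
           lp_coef_4 = 0, lp_coef_5 = 0)
  n <- length(x)
  if (n <= 5) return(out)
  xm <- x - mean(x)
  r <- vapply(0:5, function(k) {
    sum(xm[seq_len(n - k)] * xm[(1 + k):n]) / n
  }, numeric(1))
  if (r[1] < EPS) return(out)
  a <- tryCatch(solve(stats::toeplitz(r[1:5]), r[2:6]),
                error = function(e) NULL)
  if (is.null(a)) return(out)
  out["lp_gain"] <- max(0, r[1] - sum(a * r[2:6]))
  out[paste0("lp_coef_", 1:5)] <- a
  out
}

# All 54 functionals of one contour, named canonically.
compute_all_functionals <- function(x) {
  c(percentiles_block(x), temporal_block(x), moments_block(x),
    modulation_block(x), peaks_block(x), regression_block(x))
}

# Regression delta of every column of a contour matrix at once.
delta_matrix <- function(M) {
  n <- nrow(M)
  if (n < 2) return(M * 0)
  xp <- rbind(M[1, ], M[1, ], M, M[n, ], M[n, ])
  t <- seq_len(n) + 2
  ((xp[t + 1, , drop = FALSE] - xp[t - 1, , drop = FALSE]) +
      2 * (xp[t + 2, , drop = FALSE] - xp[t - 2, , drop = FALSE])) / 10
}

# Batched evaluation of the full bank over the columns of a contour
# matrix (compiled); numerically equivalent to compute_all_functionals()
# per column, which remains the reference implementation.
functional_bank_matrix <- function(M) {
  cpp_bank(M)
}
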