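# The feature index: the versioned manifest mapping every dimension of the
# suprasegmental feature vector to its (LLD, functional, delta) triple.
#
# Composition rules (manifest version 1), yielding exactly 6373 dimensions:
#   * every functional is applied to each of the 64 LLD contours and their
#     regression deltas (128 contours x 54 functionals), except
#   * percentage-of-non-zero-frames is computed only on the F0 contour,
#     the one descriptor whose zeros are categorical (unvoiced);
#   * segment-length statistics are not computed on delta contours
#     (segments are defined by level thresholds, which a differenced
#     contour does not carry);
#   * linear-prediction (modulation) functionals are not computed on the
#     deltas of the 26 auditory band trajectories, which are themselves
#     the output of a band-pass filter along time.
# 128 * 54 - 127 - 4 * 64 - 6 * 26 = 6373.

FEATURE_INDEX_VERSION <- 1L

#' Names, families and application blocks of the 54 functionals
#'
#' @return data.frame with columns `name`, `family` (one of percentiles,
#'   temporal, moments, modulation, peaks, regression) and `applies_to`
#'   (`"lld_and_delta"` or `"lld_only"`, the two sections of the bank).
#' @export
functional_info <- function() {
  a <- list(
    c("quartile_1", "percentiles"), c("quartile_2", "percentiles"),
    c("quartile_3", "percentiles"), c("iqr_1_2", "percentiles"),
    c("iqr_2_3", "percentiles"), c("iqr_1_3", "percentiles"),
    c("percentile_1", "percentiles"), c("percentile_99", "percentiles"),
    c("range_1_99", "percentiles"),
    c("pos_min", "temporal"), c("pos_max", "temporal"),
    c("range", "temporal"),
    c("amean", "moments"), c("rqmean", "moments"),
    c("contour_centroid", "temporal"), c("flatness", "temporal"),
    c("stddev", "moments"), c("skewness", "moments"),
    c("kurtosis", "moments"),
    c("up25_duration", "temporal"), c("up50_duration", "temporal"),
    c("up75_duration", "temporal"), c("up90_duration", "temporal"),
    c("rise_duration", "temporal"), c("curvature_duration", "temporal"),
    c("lp_gain", "modulation"), c("lp_coef_1", "modulation"),
    c("lp_coef_2", "modulation"), c("lp_coef_3", "modulation"),
    c("lp_coef_4", "modulation"), c("lp_coef_5", "modulation"),
    c("seglen_mean", "temporal"), c("seglen_max", "temporal"),
    c("seglen_min", "temporal"), c("seglen_sd", "temporal"))
  b <- list(
    c("peak_mean", "peaks"), c("peak_mean_rel", "peaks"),
    c("peak_dist_mean", "peaks"), c("peak_dist_sd", "peaks"),
    c("peak_amp_mean", "peaks"), c("min_amp_mean", "peaks"),
    c("peak_amp_range", "peaks"),
    c("rise_slope_mean", "peaks"), c("rise_slope_sd", "peaks"),
    c("fall_slope_mean", "peaks"), c("fall_slope_sd", "peaks"),
    c("linreg_slope", "regression"), c("linreg_offset", "regression"),
    c("linreg_err", "regression"),
    c("quadreg_a", "regression"), c("quadreg_b", "regression"),
    c("quadreg_offset", "regression"), c("quadreg_err", "regression"),
    c("pct_nonzero", "temporal"))
  all <- c(a, b)
  data.frame(name = vapply(all, `[`, "", 1),
             family = vapply(all, `[`, "", 2),
             applies_to = c(rep("lld_and_delta", length(a)),
                            rep("lld_only", length(b))),
             stringsAsFactors = FALSE)
}

#' The feature index (manifest) of the full feature set
#'
#' Enumerates the 6373 dimensions of the suprasegmental feature vector:
#' one row per dimension with the LLD it summarizes, the LLD's group and
#' block labels, the functional and its family, and the delta flag.
#' Stable-ordered (LLD-major, plain contour before delta, functionals in
#' canonical order) so that downstream selections and reports are
#' reproducible.
#'
#' @return data.frame with attributes `version`; columns `name`,
#'   `lld_name`, `lld_group`, `lld_block`, `functional_name`,
#'   `functional_family`, `is_delta`.
#' @export
feature_index <- function() {
  cached("feature_index_v1", build_feature_index)
}

build_feature_index <- function() {
  lld <- lld_info()
  fi <- functional_info()
  rows <- vector("list", 128L)
  k <- 0L
  for (i in seq_len(nrow(lld))) {
    for (delta in c(FALSE, TRUE)) {
      keep <- rep(TRUE, nrow(fi))
      keep[fi$name == "pct_nonzero"] <-
        (lld$name[i] == "f0") && !delta
      if (delta) {
        keep[startsWith(fi$name, "seglen_")] <- FALSE
        if (startsWith(lld$name[i], "rasta_band_")) {
          keep[fi$family == "modulation"] <- FALSE
        }
      }
      f <- fi[keep, , drop = FALSE]
      k <- k + 1L
      rows[[k]] <- data.frame(
        name = paste0(lld$name[i], if (delta) "_de" else "", "__", f$name),
        lld_name = lld$name[i], lld_group = lld$group[i],
        lld_block = lld$block[i], functional_name = f$name,
        functional_family = f$family, is_delta = delta,
        stringsAsFactors = FALSE)
    }
  }
  idx <- do.call(rbind, rows)
  rownames(idx) <- NULL
  attr(idx, "version") <- FEATURE_INDEX_VERSION
  idx
}

#' Apply the functional bank to an LLD matrix
#'
#' Computes every dimension of the feature index from the 64 contours and
#' their deltas.  Deterministic; any non-finite cell raises an error naming
#' the offending dimension.
#'
#' @param lld an `lld_matrix` from [extract_lld()].
#' @param index the manifest from [feature_index()] (passed in so a subset
#'   can be computed, e.g. for selected features).
#' @return named numeric vector with one value per index row and attribute
#'   `clip_id`.
#' @export
extract_features <- function(lld, index = feature_index()) {
  vals <- lld$values
  if (!all(lld$names %in% colnames(vals)) ||
      !all(unique(index$lld_name) %in% colnames(vals))) {
    stop("feature index inconsistent with LLD matrix columns")
  }
  llds <- unique(index$lld_name)
  base <- vals[, llds, drop = FALSE]
  M <- cbind(base, delta_matrix(base))
  colnames(M) <- c(llds, paste0(llds, "_de"))
  bank <- functional_bank_matrix(M)
  rowk <- match(paste0(index$lld_name, ifelse(index$is_delta, "_de", "")),
                rownames(bank))
  colk <- match(index$functional_name, colnames(bank))
  out <- bank[cbind(rowk, colk)]
  names(out) <- index$name
  bad <- which(!is.finite(out))
  if (length(bad) > 0) {
    stop("non-finite feature value in dimension '", names(out)[bad[1]],
         "' of clip '", lld$clip_id, "'")
  }
  attr(out, "clip_id") <- lld$clip_id
  out
}

#' Feature matrix for a list of clips
#'
#' Convenience wrapper running [extract_lld()] and [extract_features()]
#' over a clip list.
#'
#' @param clips list of [audio_clip()] objects.
#' @param index manifest from [feature_index()].
#' @param config an [lld_config()].
#' @param verbose log progress to stderr.
#' @return numeric matrix, clips x dimensions, rownames = clip ids.
#' @export
extract_feature_matrix <- function(clips, index = feature_index(),
                                   config = lld_config(), verbose = FALSE) {
  mat <- matrix(0, length(clips), nrow(index),
                dimnames = list(vapply(clips, function(cl) cl$clip_id, ""),
                                index$name))
  for (i in seq_along(clips)) {
    if (verbose && i %% 50 == 0) {
      stage_log("extracted %d/%d clips", i, length(clips))
    }
    mat[i, ] <- extract_features(extract_lld(clips[[i]]), index)
  }
  mat
}

#' Write the feature index manifest as JSON
#'
#' @param index manifest from [feature_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_manifest <- function(index, path) {
  jsonlite::write_json(
    list(version = attr(index, "version"), n_dimensions = nrow(index),
         dimensions = index),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
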