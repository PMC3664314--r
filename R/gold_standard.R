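# Fusion of multi-rater affect annotations into an evaluator-weighted
# estimator (EWE) gold standard, with agreement statistics.

#' Construct a rating matrix
#'
#' @param values numeric matrix, instances x raters; `NA` marks a missing
#'   rating.
#' @param scale `"continuous"` (values in \[-1, 1\]) or `"five_point"`
#'   (values in -2..2).
#' @param rater_ids optional rater names.
#' @return object of class `rating_matrix`.
#' @export
rating_matrix <- function(values, scale = c("continuous", "five_point"),
                          rater_ids = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (ncol(values) < 1) stop("rating_matrix: need at least one rater")
  if (is.null(rater_ids)) {
    rater_ids <- colnames(values)
    if (is.null(rater_ids)) rater_ids <- paste0("rater_", seq_len(ncol(values)))
  }
  colnames(values) <- rater_ids
  check_scale(values, scale)
  structure(list(values = values, scale = scale, rater_ids = rater_ids),
            class = "rating_matrix")
}

check_scale <- function(values, scale) {
  obs <- values[!is.na(values)]
  bad <- if (scale == "five_point") {
    !obs %in% c(-2, -1, 0, 1, 2)
  } else {
    obs < -1 | obs > 1
  }
  if (any(bad)) {
    idx <- which(!is.na(values))[which(bad)[1]]
    rc <- arrayInd(idx, dim(values))
    stop(sprintf(
      "rating out of declared '%s' scale: value %g (instance %d, rater %s)",
      scale, values[idx], rc[1],
      colnames(values)[rc[2]] %||% as.character(rc[2])))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map ratings onto the common \[-1, 1\] scale
#'
#' Five-point ratings in -2..2 map linearly onto
#' \{-1, -0.5, 0, 0.5, 1\}; continuous ratings pass through unchanged.
#'
#' @param m a [rating_matrix()].
#' @return a `rating_matrix` on the continuous scale.
#' @export
map_scale <- function(m) {
  stopifnot(inherits(m, "rating_matrix"))
  if (m$scale == "continuous") return(m)
  rating_matrix(m$values / 2, "continuous", m$rater_ids)
}

#' Per-rater confidence
#'
#' The confidence of rater k is the Pearson correlation of that rater's
#' ratings with the across-rater mean rating (computed over the instances
#' the rater annotated).  A zero-variance rater, or a degenerate constant
#' mean column, yields confidence 0 with a warning.
#'
#' @param m a [rating_matrix()] (mapped to \[-1, 1\] first if needed).
#' @return numeric vector of confidences r_k, one per rater.
#' @export
rater_confidence <- function(m) {
  m <- map_scale(m)
  v <- m$values
  if (ncol(v) < 2) return(stats::setNames(1, m$rater_ids))
  mean_col <- rowMeans(v, na.rm = TRUE)
  r <- vapply(seq_len(ncol(v)), function(k) {
    ok <- !is.na(v[, k])
    if (sum(ok) < 3 || safe_sd(v[ok, k]) < EPS || safe_sd(mean_col[ok]) < EPS) {
      warning("degenerate rater '", m$rater_ids[k],
              "': confidence set to 0", call. = FALSE)
      return(0)
    }
    stats::cor(v[ok, k], mean_col[ok])
  }, numeric(1))
  stats::setNames(r, m$rater_ids)
}

#' Evaluator weighted estimator (EWE) fusion
#'
#' Fuses a rating matrix into one gold-standard value per instance: a
#' weighted mean of the raters' values with weights proportional to each
#' rater's confidence, normalized to sum to one so the fusion stays on the
#' rating scale.  Negative confidences are clamped to zero before
#' normalization (a negative weight could push the fusion outside the
#' raters' value range); missing ratings drop the rater for that instance
#' with per-instance weight renormalization.
#'
#' @param m a [rating_matrix()].
#' @param confidence optional per-rater confidences; computed by
#'   [rater_confidence()] when omitted.
#' @return object of class `ewe_gold`: list with `ewe` (per-instance
#'   fusion), `rater_confidence`, `mean_agreement`.
#' @export
ewe <- function(m, confidence = NULL) {
  m <- map_scale(m)
  v <- m$values
  if (is.null(confidence)) confidence <- rater_confidence(m)
  w <- pmax(confidence, 0)
  if (sum(w) <= 0) stop("EWE undefined: all rater confidences <= 0")
  wm <- matrix(w, nrow(v), ncol(v), byrow = TRUE)
  wm[is.na(v)] <- 0
  v0 <- v
  v0[is.na(v)] <- 0
  denom <- rowSums(wm)
  if (any(denom <= 0)) {
    stop("EWE undefined for instance(s) without usable ratings: ",
         paste(which(denom <= 0)[1:min(3, sum(denom <= 0))], collapse = ", "))
  }
  structure(list(ewe = rowSums(wm * v0) / denom,
                 rater_confidence = confidence,
                 mean_agreement = mean(confidence)),
            class = "ewe_gold")
}

#' @export
print.ewe_gold <- function(x, ...) {
  cat(sprintf("<ewe_gold: %d instances, %d raters, mean agreement r = %.2f>\n",
              length(x$ewe), length(x$rater_confidence), x$mean_agreement))
  invisible(x)
}

#' Two-dimensional binning of the gold standard
#'
#' Counts instances over an equally spaced bins x bins grid spanning
#' \[-1, 1\] in both affect dimensions.  Bins are right-closed; the lowest
#' bin includes -1, so the boundary value +1 falls in the top bin.
#'
#' @param arousal,valence gold-standard vectors on \[-1, 1\].
#' @param bins number of bins per axis.
#' @return integer matrix (arousal bins x valence bins, low to high) whose
#'   entries sum to the instance count.
#' @export
bin_2d <- function(arousal, valence, bins = 5) {
  stopifnot(length(arousal) == length(valence),
            all(abs(arousal) <= 1), all(abs(valence) <= 1))
  edges <- seq(-1, 1, length.out = bins + 1)
  cut2 <- function(x) {
    as.integer(cut(x, edges, include.lowest = TRUE, right = TRUE))
  }
  tab <- table(factor(cut2(arousal), levels = seq_len(bins)),
               factor(cut2(valence), levels = seq_len(bins)))
  m <- matrix(as.integer(tab), bins, bins,
              dimnames = list(arousal = NULL, valence = NULL))
  m
}

#' Read a long-format ratings CSV
#'
#' Expected columns: `instance_id`, `rater_id`, `arousal`, `valence`.
#'
#' @param path CSV path.
#' @param scale declared rating scale, see [rating_matrix()].
#' @return list with `arousal` and `valence` [rating_matrix()] objects and
#'   `instance_ids`.
#' @export
read_ratings_csv <- function(path, scale = "continuous") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("instance_id", "rater_id", "arousal", "valence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("ratings CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  inst <- unique(df$instance_id)
  raters <- unique(df$rater_id)
  build <- function(col) {
    m <- matrix(NA_real_, length(inst), length(raters),
                dimnames = list(inst, raters))
    m[cbind(match(df$instance_id, inst), match(df$rater_id, raters))] <- df[[col]]
    rating_matrix(m, scale, raters)
  }
  list(arousal = build("arousal"), valence = build("valence"),
       instance_ids = inst)
}

#' Fuse both affect dimensions and report agreement
#'
#' @param ratings list with `arousal` and `valence` [rating_matrix()]
#'   objects (e.g. from [read_ratings_csv()]).
#' @return object of class `gold_standard`: data.frame `gold`
#'   (instance-wise EWE per dimension) plus per-dimension `agreement`.
#' @export
gold_standard <- function(ratings) {
  a <- ewe(ratings$arousal)
  v <- ewe(ratings$valence)
  structure(list(
    gold = data.frame(instance_id = ratings$instance_ids %||%
                        seq_along(a$ewe),
                      arousal = a$ewe, valence = v$ewe),
    agreement = list(arousal = a, valence = v)),
    class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf(
    "<gold_standard: %d instances; mean agreement arousal %.2f, valence %.2f>\n",
    nrow(x$gold), x$agreement$arousal$mean_agreement,
    x$agreement$valence$mean_agreement))
  invisible(x)
}
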