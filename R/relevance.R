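# Feature relevance: per-domain correlations, significance with Bonferroni
# correction, the cross-domain correlation coefficient (CDCC), top-k
# selection, and group-share summaries.

#' Per-feature correlation with a gold-standard rating
#'
#' Pearson correlation of every feature column with the rating vector.
#' Zero-variance features get r = 0 and are flagged.
#'
#' @param features numeric matrix, instances x features.
#' @param rating numeric gold-standard vector.
#' @return numeric vector of correlations with attribute `flagged`
#'   (logical, TRUE for degenerate features).
#' @export
feature_correlation <- function(features, rating) {
  stopifnot(nrow(features) == length(rating), nrow(features) >= 3)
  if (safe_sd(rating) < EPS) stop("rating has zero variance")
  sds <- apply(features, 2, safe_sd)
  flagged <- sds < EPS
  r <- suppressWarnings(as.numeric(stats::cor(features, rating)))
  r[flagged | !is.finite(r)] <- 0
  structure(r, names = colnames(features), flagged = flagged)
}

#' Significance of a correlation under the independence null
#'
#' Two-sided t-test of r against the null that feature and rating are
#' sampled from independent normal distributions:
#' t = r sqrt((n-2)/(1-r^2)) with n-2 degrees of freedom.  P-values are
#' Bonferroni-adjusted by the number of tests and capped at 1.
#'
#' @param r correlation(s).
#' @param n sample size.
#' @param m_tests Bonferroni factor (e.g. the feature-set dimensionality).
#' @param levels significance thresholds for the star labels.
#' @return data.frame with `r`, `p`, `p_adj`, `stars`.
#' @export
significance <- function(r, n, m_tests = 1,
                         levels = c(`***` = 0.001, `**` = 0.01, `*` = 0.05)) {
  stopifnot(n >= 3)
  r2 <- pmin(r^2, 1)
  t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, EPS))
  p <- ifelse(r2 >= 1, 0, 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE))
  p_adj <- pmin(p * m_tests, 1)
  lv <- sort(levels)
  stars <- rep("", length(r))
  for (i in rev(seq_along(lv))) stars[p_adj < lv[i]] <- names(lv)[i]
  data.frame(r = r, p = p, p_adj = p_adj, stars = stars,
             stringsAsFactors = FALSE)
}

#' Pairwise cross-domain correlation coefficient
#'
#' CDCC of a feature across two domains i and j:
#' (|r_i + r_j| - |r_i - r_j|) / 2, which equals
#' sign(r_i r_j) min(|r_i|, |r_j|).  It is symmetric, lies in \[-1, 1\],
#' is near 1 when the feature correlates strongly with the same sign in
#' both domains, and near -1 when the signs oppose.
#'
#' @param r_i,r_j correlations in the two domains (vectorized).
#' @return numeric vector of pairwise CDCC values.
#' @export
cdcc2 <- function(r_i, r_j) {
  if (any(abs(r_i) > 1 + 1e-8) || any(abs(r_j) > 1 + 1e-8)) {
    stop("cdcc2: correlations must lie in [-1, 1]")
  }
  (abs(r_i + r_j) - abs(r_i - r_j)) / 2
}

#' Multi-domain cross-domain correlation coefficient
#'
#' Generalizes the pairwise CDCC to J domains by summing the pairwise
#' terms over all domain pairs and normalizing by J(J-1), so the value
#' stays in \[-1, 1\] and reduces to [cdcc2()] at J = 2.  Equals the mean
#' of the pairwise CDCCs.
#'
#' @param r per-domain correlations: a numeric vector (one feature) or a
#'   matrix with one column per domain (features x domains).
#' @return numeric vector of CDCC^J values.
#' @export
cdccJ <- function(r) {
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  J <- ncol(r)
  if (J < 2) stop("cdccJ: need at least two domains")
  acc <- numeric(nrow(r))
  for (i in seq_len(J - 1)) {
    for (j in (i + 1):J) {
      acc <- acc + abs(r[, i] + r[, j]) - abs(r[, i] - r[, j])
    }
  }
  acc / (J * (J - 1))
}

#' Relevance table across domains
#'
#' Per feature: correlation with the rating in each domain, Bonferroni
#' adjusted significance, every pairwise CDCC, and the pooled CDCC across
#' all domains.
#'
#' @param datasets named list of domain datasets, each a list with
#'   `features` (instances x features, shared column order) and the gold
#'   vectors `arousal` and `valence`.
#' @param dimension `"arousal"` or `"valence"`.
#' @param m_tests Bonferroni factor; defaults to the feature count.
#' @return data.frame of class `relevance_table`: `feature`, `r_<domain>`,
#'   `stars_<domain>`, `cdcc2_<i>_<j>`, `cdccJ`.
#' @export
relevance_table <- function(datasets, dimension = c("arousal", "valence"),
                            m_tests = NULL) {
  dimension <- match.arg(dimension)
  doms <- names(datasets)
  stopifnot(length(doms) >= 2)
  feats <- colnames(datasets[[1]]$features)
  if (is.null(m_tests)) m_tests <- length(feats)
  rmat <- sapply(datasets, function(d) {
    feature_correlation(d$features, d[[dimension]])
  })
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (d in doms) {
    sig <- significance(rmat[, d], nrow(datasets[[d]]$features), m_tests)
    out[[paste0("r_", d)]] <- rmat[, d]
    out[[paste0("stars_", d)]] <- sig$stars
  }
  for (i in seq_along(doms)[-length(doms)]) {
    for (j in (i + 1):length(doms)) {
      out[[paste0("cdcc2_", doms[i], "_", doms[j])]] <-
        cdcc2(rmat[, i], rmat[, j])
    }
  }
  out$cdccJ <- cdccJ(rmat)
  class(out) <- c("relevance_table", "data.frame")
  attr(out, "dimension") <- dimension
  out
}

#' @export
print.relevance_table <- function(x, n = 10, ...) {
  cat(sprintf("<relevance_table [%s]: %d features x %d domains>\n",
              attr(x, "dimension"), nrow(x),
              sum(startsWith(names(x), "r_"))))
  ord <- order(-x$cdccJ)
  print.data.frame(utils::head(x[ord, ], n), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Select the top-k features by a relevance criterion
#'
#' Descending sort on the criterion with ties broken by manifest order
#' (the row order of the table), so selections are reproducible.
#'
#' @param table a [relevance_table()] (or any data.frame with a `feature`
#'   column and the criterion column).
#' @param criterion column name to rank by (e.g. `"cdccJ"`, a
#'   `"cdcc2_i_j"` column) or `"abs_r_<domain>"` for single-domain
#'   absolute correlation.
#' @param k subset size.
#' @return character vector of k feature names, ranked.
#' @export
select_top_k <- function(table, criterion = "cdccJ", k = 200) {
  stopifnot(k <= nrow(table))
  score <- if (startsWith(criterion, "abs_")) {
    abs(table[[sub("^abs_", "", criterion)]])
  } else {
    table[[criterion]]
  }
  if (is.null(score)) stop("unknown criterion column: ", criterion)
  table$feature[order(-score, seq_len(nrow(table)))][seq_len(k)]
}

#' Single-domain feature selection by split-half CDCC
#'
#' Splits one domain's instances into random disjoint halves (seeded),
#' correlates every feature with the rating in each half, and ranks by the
#' pairwise CDCC of the two half correlations — rewarding features whose
#' relation to the rating replicates within the domain.
#'
#' @param features instances x features matrix.
#' @param rating gold-standard vector.
#' @param k subset size.
#' @param seed integer seed for the split.
#' @return character vector of k feature names, ranked; attribute `cdcc2`
#'   carries the full criterion vector.
#' @export
split_half_selection <- function(features, rating, k = 200, seed = 1) {
  n <- nrow(features)
  stopifnot(n >= 4)
  half <- with_seed(seed, sample(n, floor(n / 2)))
  r1 <- feature_correlation(features[half, , drop = FALSE], rating[half])
  r2 <- feature_correlation(features[-half, , drop = FALSE], rating[-half])
  crit <- cdcc2(as.numeric(r1), as.numeric(r2))
  sel <- colnames(features)[order(-crit, seq_len(ncol(features)))][seq_len(k)]
  attr(sel, "cdcc2") <- stats::setNames(crit, colnames(features))
  sel
}

#' Group shares of a feature subset
#'
#' Counts a selected subset by LLD group and by functional family, against
#' the full-set baselines.  A group is flagged enriched when its share of
#' the subset exceeds its share of the full set.
#'
#' @param subset character vector of selected feature names.
#' @param index manifest from [feature_index()].
#' @return list of class `group_shares` with data.frames `lld_group` and
#'   `functional_family` (`count`, `share`, `baseline_count`,
#'   `baseline_share`, `enriched`).
#' @export
group_shares <- function(subset, index = feature_index()) {
  pos <- match(subset, index$name)
  if (anyNA(pos)) stop("subset contains features not in the index: ",
                       subset[which(is.na(pos))[1]])
  one <- function(col) {
    base <- table(index[[col]])
    sel <- table(factor(index[[col]][pos], levels = names(base)))
    data.frame(group = names(base),
               count = as.integer(sel),
               share = as.numeric(sel) / length(pos),
               baseline_count = as.integer(base),
               baseline_share = as.numeric(base) / nrow(index),
               enriched = as.numeric(sel) / length(pos) >
                 as.numeric(base) / nrow(index),
               stringsAsFactors = FALSE)
  }
  structure(list(lld_group = one("lld_group"),
                 functional_family = one("functional_family"),
                 n_selected = length(pos)),
            class = "group_shares")
}

#' @export
print.group_shares <- function(x, ...) {
  cat(sprintf("<group_shares of %d selected features>\n", x$n_selected))
  cat("by LLD group:\n")
  print.data.frame(x$lld_group, digits = 3, row.names = FALSE)
  cat("by functional family:\n")
  print.data.frame(x$functional_family, digits = 3, row.names = FALSE)
  invisible(x)
}
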