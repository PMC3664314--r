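# Linear epsilon support-vector regression with per-database
# normalization, twofold within-domain cross-validation, and the
# cross-domain train/test grid.

#' Per-database mean/variance normalization
#'
#' Unsupervised z-normalization of each feature column.  When `stats` is
#' omitted they are estimated from `features` itself — each database is
#' normalized with its own statistics, train and test alike.
#' Zero-variance features map to 0.
#'
#' @param features instances x features matrix.
#' @param stats optional list with `mean` and `sd` per feature.
#' @return list with `features` (normalized) and `stats`.
#' @export
znormalize <- function(features, stats = NULL) {
  if (is.null(stats)) {
    stats <- list(mean = colMeans(features),
                  sd = apply(features, 2, safe_sd))
  }
  sd_safe <- ifelse(stats$sd < EPS, 1, stats$sd)
  z <- sweep(sweep(features, 2, stats$mean, "-"), 2, sd_safe, "/")
  z[, stats$sd < EPS] <- 0
  list(features = z, stats = stats)
}

#' Fit a linear epsilon-SVR
#'
#' Support-vector regression with a linear kernel: the flattest affine
#' function f(x) = w'x + b whose deviations from the targets beyond the
#' epsilon tube are penalized at rate C.  Solved by the SMO-type solver of
#' libsvm (via e1071); deterministic for fixed input and tolerance.
#'
#' @param features normalized instances x features matrix.
#' @param targets numeric target vector.
#' @param C complexity constant (default 1e-5, the pipeline-wide value).
#' @param epsilon tube half-width.
#' @param tolerance solver termination tolerance.
#' @return object of class `affect_svr` with weights `w`, offset `b`, and
#'   the fit constants.
#' @export
fit_svr <- function(features, targets, C = 1e-5, epsilon = 0.1,
                    tolerance = 1e-3) {
  stopifnot(nrow(features) >= 2, nrow(features) == length(targets))
  if (any(!is.finite(targets))) stop("non-finite regression target")
  fit <- e1071::svm(x = features, y = targets, scale = FALSE,
                    type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = epsilon, tolerance = tolerance,
                    fitted = FALSE)
  w <- stats::setNames(numeric(ncol(features)), colnames(features))
  if (fit$tot.nSV > 0) {
    w[] <- as.numeric(crossprod(fit$SV, fit$coefs))
  }
  structure(list(w = w, b = -fit$rho, C = C, epsilon = epsilon,
                 tolerance = tolerance, n_sv = fit$tot.nSV),
            class = "affect_svr")
}

#' @export
predict.affect_svr <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w + object$b)
}

#' @export
coef.affect_svr <- function(object, ...) {
  c(`(offset)` = object$b, object$w)
}

#' @export
print.affect_svr <- function(x, ...) {
  cat(sprintf(
    "<affect_svr: %d features, C = %g, epsilon = %g, ||w|| = %.3g, b = %.3g>\n",
    length(x$w), x$C, x$epsilon, sqrt(sum(x$w^2)), x$b))
  invisible(x)
}

#' Correlation of model predictions with a gold standard
#'
#' @param model an `affect_svr`.
#' @param features test instances x features (normalized with the test
#'   database's own statistics).
#' @param gold gold-standard vector.
#' @return Pearson r; 0 with a `degenerate` attribute when predictions are
#'   constant.
#' @export
evaluate <- function(model, features, gold) {
  stopifnot(ncol(features) == length(model$w))
  safe_cor(predict(model, features), gold)
}

#' Within-domain twofold cross-validated correlation
#'
#' Splits the database into random halves (seeded), trains on each half
#' and predicts the other, and reports one Pearson r over the pooled
#' predictions.
#'
#' @param features instances x features (normalized once per database).
#' @param targets gold-standard vector.
#' @param C,epsilon SVR constants, see [fit_svr()].
#' @param seed integer seed for the split.
#' @return Pearson r of pooled predictions against the gold standard.
#' @export
within_domain_cv <- function(features, targets, C = 1e-5, epsilon = 0.1,
                             seed = 1) {
  n <- nrow(features)
  stopifnot(n >= 4)
  half <- with_seed(seed, sample(n, floor(n / 2)))
  folds <- list(half, setdiff(seq_len(n), half))
  preds <- numeric(n)
  for (f in folds) {
    fit <- fit_svr(features[-f, , drop = FALSE], targets[-f], C, epsilon)
    preds[f] <- predict(fit, features[f, , drop = FALSE])
  }
  safe_cor(preds, targets)
}

#' Cross-domain train/test evaluation grid
#'
#' For every ordered pair of domains, trains a linear SVR on the training
#' domain and reports the correlation of its predictions with the test
#' domain's gold standard; diagonal cells are within-domain twofold
#' cross-validation.  Each database is z-normalized with its own
#' statistics.  Three feature-set conditions are supported: the full set,
#' per-pair task-specific top-k sets (ranked by the pair's CDCC; diagonal
#' cells use the domain's split-half selection), and one generic top-k set
#' ranked by the pooled CDCC across all domains.
#'
#' @param datasets named list of domain datasets (`features` plus gold
#'   vectors, see [relevance_table()]).
#' @param dimension `"arousal"` or `"valence"`.
#' @param feature_set `"full"`, `"task_specific"` or `"generic"`.
#' @param k selection size for the selected-set conditions.
#' @param C,epsilon SVR constants.
#' @param seed seed for the cross-validation and split-half partitions.
#' @return object of class `eval_grid`: the r matrix (rows = training
#'   domain, columns = test domain) with the condition label; means are
#'   recomputed from the entries by [grand_mean()] and friends.
#' @export
cross_domain_grid <- function(datasets, dimension = c("arousal", "valence"),
                              feature_set = c("full", "task_specific",
                                              "generic"),
                              k = 200, C = 1e-5, epsilon = 0.1, seed = 1) {
  dimension <- match.arg(dimension)
  feature_set <- match.arg(feature_set)
  doms <- names(datasets)
  J <- length(doms)
  stopifnot(J >= 2)
  norm <- lapply(datasets, function(d) znormalize(d$features)$features)
  gold <- lapply(datasets, function(d) d[[dimension]])
  rel <- if (feature_set != "full") {
    relevance_table(datasets, dimension)
  }
  subset_for <- function(i, j) {
    if (feature_set == "full") {
      colnames(datasets[[1]]$features)
    } else if (feature_set == "generic") {
      select_top_k(rel, "cdccJ", k)
    } else if (i == j) {
      split_half_selection(datasets[[i]]$features, gold[[i]], k,
                           seed = derive_seed(seed, i))
    } else {
      a <- min(i, j); b <- max(i, j)
      select_top_k(rel, paste0("cdcc2_", doms[a], "_", doms[b]), k)
    }
  }
  r <- matrix(NA_real_, J, J, dimnames = list(train = doms, test = doms))
  for (i in seq_len(J)) {
    for (j in seq_len(J)) {
      sel <- subset_for(i, j)
      if (i == j) {
        r[i, j] <- within_domain_cv(norm[[i]][, sel, drop = FALSE],
                                    gold[[i]], C, epsilon,
                                    seed = derive_seed(seed, 100 + i))
      } else {
        fit <- fit_svr(norm[[i]][, sel, drop = FALSE], gold[[i]], C, epsilon)
        r[i, j] <- evaluate(fit, norm[[j]][, sel, drop = FALSE], gold[[j]])
      }
    }
  }
  structure(list(r = r, dimension = dimension, feature_set = feature_set,
                 k = if (feature_set == "full") ncol(datasets[[1]]$features)
                     else k,
                 C = C, epsilon = epsilon, seed = seed),
            class = "eval_grid")
}

#' Row, column and grand means of an evaluation grid
#'
#' Always recomputed from the grid entries.
#'
#' @param grid an `eval_grid` (or a bare r matrix).
#' @return numeric.
#' @export
grand_mean <- function(grid) mean(grid_matrix(grid))

#' @rdname grand_mean
#' @export
row_means <- function(grid) rowMeans(grid_matrix(grid))

#' @rdname grand_mean
#' @export
col_means <- function(grid) colMeans(grid_matrix(grid))

grid_matrix <- function(grid) {
  if (inherits(grid, "eval_grid")) grid$r else as.matrix(grid)
}

#' Construct an evaluation grid from a plain r matrix
#'
#' Useful for aggregating externally reported grids with the same
#' row/column conventions.
#'
#' @param r square matrix of correlations (rows = training domain).
#' @param dimension,feature_set labels.
#' @return an `eval_grid`.
#' @export
eval_grid <- function(r, dimension = "arousal", feature_set = "full") {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), all(abs(r) <= 1))
  structure(list(r = r, dimension = dimension, feature_set = feature_set,
                 k = NA_integer_, C = NA_real_, epsilon = NA_real_,
                 seed = NA_integer_),
            class = "eval_grid")
}

#' @export
print.eval_grid <- function(x, ...) {
  cat(sprintf("<eval_grid [%s, %s features]>\n", x$dimension, x$feature_set))
  m <- cbind(x$r, mean = row_means(x))
  m <- rbind(m, mean = c(col_means(x), grand_mean(x)))
  print(round(m, 2))
  invisible(x)
}
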