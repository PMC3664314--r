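# End-to-end orchestration: extraction -> gold standard -> relevance and
# selection -> regression grid, with provenance-stamped artifacts.

#' Run the full cross-domain affect pipeline
#'
#' Builds the domain datasets (from a synthetic configuration or from
#' declared audio directories with ratings CSVs), extracts the feature
#' matrix, fuses the rater annotations into the EWE gold standard, ranks
#' features by CDCC, and evaluates linear SVR within and across domains
#' for the requested feature-set conditions.  Idempotent for a fixed
#' configuration; every written artifact carries the configuration hash.
#'
#' @param config a [synth_config()], or a list with a `datasets` element:
#'   each entry a list with `audio_dir`, `ratings_csv`, `domain`, `scale`.
#' @param feature_sets conditions to evaluate, subset of
#'   `c("full", "task_specific", "generic")`.
#' @param k selection size for the selected-set conditions.
#' @param C SVR complexity constant.
#' @param seed seed for cross-validation splits (synthetic generation uses
#'   the seed inside `config`).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param verbose log stage timings to stderr.
#' @return object of class `affect_report`: `datasets` (features + gold),
#'   `gold`, `relevance` and `grids` per affect dimension, `selection`
#'   lists, `config_hash`.
#' @export
run_pipeline <- function(config = synth_config(),
                         feature_sets = c("full", "generic"),
                         k = 200, C = 1e-5, seed = 1,
                         out_dir = NULL, verbose = TRUE) {
  feature_sets <- match.arg(feature_sets,
                            c("full", "task_specific", "generic"),
                            several.ok = TRUE)
  t0 <- Sys.time()
  say <- function(...) if (verbose) stage_log(...)
  index <- feature_index()
  datasets <- build_datasets(config, index, say)
  hash <- config_hash(if (inherits(config, "synth_config")) unclass(config)
                      else config)

  say("relevance analysis over %d features", nrow(index))
  relevance <- list()
  grids <- list()
  selection <- list()
  for (dim in c("arousal", "valence")) {
    rel <- relevance_table(datasets, dim)
    relevance[[dim]] <- rel
    selection[[dim]] <- select_top_k(rel, "cdccJ", min(k, nrow(rel)))
    grids[[dim]] <- lapply(stats::setNames(feature_sets, feature_sets),
      function(fs) {
        say("regression grid: %s / %s features", dim, fs)
        cross_domain_grid(datasets, dim, fs, k = min(k, nrow(rel)),
                          C = C, seed = seed)
      })
  }
  report <- structure(
    list(datasets = datasets, relevance = relevance, grids = grids,
         selection = selection, k = k, C = C, config_hash = hash,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "affect_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  say("pipeline finished in %.1f s", report$elapsed_s)
  report
}

build_datasets <- function(config, index, say = stage_log) {
  if (inherits(config, "synth_config")) {
    say("generating synthetic corpus (%s)",
        paste(names(config$domains), collapse = ", "))
    corpus <- gen_corpus(config)
    datasets <- lapply(corpus, function(dom) {
      say("extracting %d clips of domain '%s'", length(dom$clips),
          dom$domain)
      feats <- extract_feature_matrix(dom$clips, index)
      gold <- gold_standard(list(arousal = dom$ratings$arousal,
                                 valence = dom$ratings$valence,
                                 instance_ids = rownames(feats)))
      list(features = feats, arousal = gold$gold$arousal,
           valence = gold$gold$valence, gold = gold)
    })
    return(datasets)
  }
  if (is.null(config$datasets)) {
    stop("experiment config must be a synth_config or declare 'datasets'")
  }
  datasets <- list()
  for (dcl in config$datasets) {
    for (f in c("audio_dir", "ratings_csv", "domain")) {
      if (is.null(dcl[[f]])) stop("dataset declaration missing field: ", f)
    }
    if (!file.exists(dcl$ratings_csv)) {
      stop("ratings_csv not found: ", dcl$ratings_csv)
    }
    ratings <- read_ratings_csv(dcl$ratings_csv,
                                scale = dcl$scale %||% "continuous")
    wavs <- file.path(dcl$audio_dir, paste0(ratings$instance_ids, ".wav"))
    missing <- !file.exists(wavs)
    if (any(missing)) stop("audio missing for instance: ",
                           ratings$instance_ids[which(missing)[1]])
    clips <- lapply(wavs, load_clip, domain = dcl$domain)
    say("extracting %d clips of domain '%s'", length(clips), dcl$domain)
    feats <- extract_feature_matrix(clips, index)
    gold <- gold_standard(ratings)
    datasets[[dcl$domain]] <- list(features = feats,
                                   arousal = gold$gold$arousal,
                                   valence = gold$gold$valence, gold = gold)
  }
  datasets
}

#' @export
print.affect_report <- function(x, ...) {
  cat(sprintf("<affect_report: %d domains, hash %s, %.1f s>\n",
              length(x$datasets), substr(x$config_hash, 1, 8), x$elapsed_s))
  for (dim in names(x$grids)) {
    for (fs in names(x$grids[[dim]])) {
      g <- x$grids[[dim]][[fs]]
      cat(sprintf("  %s / %-13s grand mean r = %.2f\n", dim, fs,
                  grand_mean(g)))
    }
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (dim in names(report$relevance)) {
    utils::write.csv(report$relevance[[dim]],
                     file.path(out_dir, paste0("relevance_", dim, ".csv")),
                     row.names = FALSE)
    writeLines(report$selection[[dim]],
               file.path(out_dir, paste0("selection_", dim, ".txt")))
  }
  grids <- lapply(report$grids, function(byfs) {
    lapply(byfs, function(g) {
      list(r = g$r, row_means = row_means(g), col_means = col_means(g),
           grand_mean = grand_mean(g), feature_set = g$feature_set,
           k = g$k, C = g$C)
    })
  })
  jsonlite::write_json(list(config_hash = report$config_hash, grids = grids),
                       file.path(out_dir, "grids.json"), auto_unbox = TRUE,
                       digits = NA)
  gold <- do.call(rbind, lapply(names(report$datasets), function(d) {
    data.frame(domain = d, instance_id = rownames(report$datasets[[d]]$features),
               arousal = report$datasets[[d]]$arousal,
               valence = report$datasets[[d]]$valence)
  }))
  utils::write.csv(gold, file.path(out_dir, "gold.csv"), row.names = FALSE)
  invisible(out_dir)
}
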