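#' @keywords internal
#' @useDynLib crossaffect, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Numerical floor used before logarithms and divisions throughout the package.
EPS <- 1e-10

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed` and
#' restores the previous RNG state afterwards, so seeded helpers do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic derivation of a child seed from a master seed and an index.
# Kept strictly below 2^31 so the result is always a valid integer seed.
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) * 69069 + as.numeric(index) * 7919 + 1) %%
               2147483647)
}

# Stable content hash for provenance manifests (md5 over JSON serialization).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

safe_sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s)) 0 else s
}

# Pearson correlation with an explicit convention for degenerate input:
# zero-variance arguments give r = 0 and a "degenerate" attribute.
safe_cor <- function(x, y) {
  if (safe_sd(x) < EPS || safe_sd(y) < EPS) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(x, y)
}

stage_log <- function(...) {
  message(sprintf("[crossaffect %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}
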