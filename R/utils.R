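# Internal helpers: seed substreams, argument checks, small numerics.

STAGE_LEVELS <- c("NC", "MCI", "AD")

#' Derive a reproducible sub-seed from a global seed and a stream name
#'
#' Every stochastic component of the pipeline draws its own seed from the
#' single global seed so that stages (generation, training, panel selection)
#' can be re-run independently yet reproducibly. The derivation is a small
#' string hash folded with the global seed modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stream character stream name, e.g. `"phantom"`, `"train"`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, keeps results in R's integer range
  h <- 5381
  for (code in utf8ToInt(stream)) {
    h <- (h * 33 + code) %% m
  }
  as.integer((h + (as.numeric(seed) %% m) * 31) %% m)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

as_stage <- function(stage) {
  f <- factor(as.character(stage), levels = STAGE_LEVELS)
  if (anyNA(f)) {
    bad <- unique(setdiff(as.character(stage), STAGE_LEVELS))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         " (expected NC, MCI, AD)", call. = FALSE)
  }
  f
}

# Run an expression under a temporary RNG state so library calls do not
# perturb the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Euclidean (L2) normalization of vectors or matrix columns
#'
#' @param x numeric vector, or matrix whose columns are normalized.
#' @param tol norms below `tol` raise an error rather than silently
#'   returning a non-unit vector.
#' @return object of the same shape with unit Euclidean norm (per column).
#' @export
l2_normalize <- function(x, tol = 1e-12) {
  if (is.matrix(x)) {
    nrm <- sqrt(colSums(x^2))
    if (any(nrm < tol)) {
      stop("cannot normalize: ", sum(nrm < tol),
           " column(s) have (near-)zero norm", call. = FALSE)
    }
    sweep(x, 2L, nrm, "/")
  } else {
    nrm <- sqrt(sum(x^2))
    if (nrm < tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
    x / nrm
  }
}

# File-content hash used by run manifests; tools::md5sum works on files only.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12), f)
  unname(tools::md5sum(f))
}
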