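# Internal helpers: seeded, side-effect-free randomness.
#
# Every stochastic operation in the package takes an explicit seed and runs
# inside with_seed(), which isolates it from (and restores) the caller's RNG
# state.  derive_seed() maps (seed, stream, index) to a distinct 32-bit seed
# so that, e.g., the tie-break stream of gene 7 never collides with the
# permutation stream of gene 7.

derive_seed <- function(seed, stream, index = 0L) {
  # exact in doubles: |seed| < 2^31, stream <= 9, index < 1e7
  as.integer((abs(as.double(seed)) + stream * 1e9 + as.double(index) * 101) %%
               2147483646) + 1L
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Run a pipeline stage, prefixing any error with the stage name so failures
# deep in a run are attributable.
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

validate_expression <- function(matrix, min_samples = 2L, what = "expression matrix") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop(what, " must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(matrix)))
    stop(what, " has duplicated gene ids")
  # duplicated sample ids are legitimate: bootstrap resamples carry them
  if (anyNA(matrix))
    stop(what, " contains missing values")
  if (ncol(matrix) < min_samples)
    stop(sprintf("%s has %d samples; at least %d required", what,
                 ncol(matrix), min_samples))
  invisible(matrix)
}

validate_tf_indices <- function(tfs, matrix) {
  if (length(tfs) == 0L) stop("TF index set is empty")
  tfs <- as.integer(tfs)
  if (anyNA(tfs) || any(tfs < 1L) || any(tfs > nrow(matrix)))
    stop("TF indices out of range")
  if (anyDuplicated(tfs)) stop("TF indices contain duplicates")
  tfs
}
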