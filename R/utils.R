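# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions never
#' disturb the caller's RNG stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Row variances without a matrixStats dependency.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# Derive a stream-specific 32-bit seed from a master seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() that never falls into the scalar-x trap (sample(5, ...) means
# sample from 1:5; sample_vec(5, ...) means the value 5).
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
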