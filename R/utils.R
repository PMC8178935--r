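# internal helpers shared across stages

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded stages never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed stream derived from one top-level seed.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 1009) %% 2147483629)
}

# row-wise max/min computed column-by-column; fast for tall matrices
row_max <- function(x) {
  out <- x[, 1L]
  if (ncol(x) > 1L) for (j in 2L:ncol(x)) out <- pmax(out, x[, j])
  out
}

row_min <- function(x) {
  out <- x[, 1L]
  if (ncol(x) > 1L) for (j in 2L:ncol(x)) out <- pmin(out, x[, j])
  out
}

# unbiased sample variance by row without apply()
row_var <- function(x) {
  n <- ncol(x)
  if (n < 2L) stopf("row variance requires at least 2 samples, got %d", n)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
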