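# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so generators are pure
#' functions of (spec, seed) without perturbing the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
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

# Derive a child seed from a base seed and an index, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 2654435761 + index * 40503) %% 2147483647)
}

# Draw from a normal truncated at zero by redraw (rejection), which
# preserves the target mean approximately rather than piling mass at 0.
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal redraw failed to converge", call. = FALSE)
  }
  out
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("%s must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("%s must be >= 0", name), call. = FALSE)
  invisible(x)
}
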