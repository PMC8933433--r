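# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded draws inside package
#' functions never disturb the caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal integral of y over grid x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Cumulative trapezoidal integral (same length as x, starts at 0).
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

# Coerce a list of vectors / matrix of memory representations to an
# N x n column matrix, checking consistent lengths.
as_memory_matrix <- function(memories, arg = "memories") {
  if (is.list(memories)) {
    lens <- lengths(memories)
    if (length(lens) == 0L) stop(arg, " is empty", call. = FALSE)
    if (length(unique(lens)) != 1L) {
      stop(arg, " contains vectors of mixed lengths: ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    }
    memories <- vapply(memories, as.numeric, numeric(lens[[1L]]))
    if (!is.matrix(memories)) memories <- matrix(memories, ncol = 1L)
  } else if (is.numeric(memories) && !is.matrix(memories)) {
    memories <- matrix(memories, ncol = 1L)
  }
  if (!is.matrix(memories) || !is.numeric(memories)) {
    stop(arg, " must be a numeric matrix or a list of numeric vectors",
         call. = FALSE)
  }
  if (anyNA(memories) || any(!is.finite(memories))) {
    stop(arg, " contains non-finite entries", call. = FALSE)
  }
  memories
}

`%||%` <- function(a, b) if (is.null(a)) b else a
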