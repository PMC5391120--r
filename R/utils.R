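# internal helpers shared across modules

#' Run an expression with a temporarily seeded RNG
#'
#' Seeds R's RNG for the duration of `expr` and restores the previous RNG
#' state afterwards, so seeded package functions do not disturb the caller's
#' random stream. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stream of child seeds from one master seed
#'
#' One user-facing seed controls every randomized component of a run; each
#' component receives its own deterministic child seed so that adding or
#' reordering components does not silently shift another component's stream.
#'
#' @param seed non-negative integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, n >= 1)
  # linear congruential fan-out (Numerical Recipes constants), kept < 2^31
  m <- 2^31
  a <- 1664525
  c <- 1013904223
  out <- integer(n)
  s <- as.double(seed %% m)
  for (i in seq_len(n)) {
    s <- (a * s + c) %% m
    out[i] <- as.integer(s)
  }
  out
}

#' Convert milliseconds to sample indices at a working rate
#'
#' Central ms-to-sample conversion used by the features module: times are
#' truncated toward zero onto the sampling grid, so a window `[start, end)`
#' in ms maps to the half-open sample range starting at `start` and stopping
#' one sample before `end`.
#'
#' @param ms numeric vector of times in milliseconds.
#' @param rate sampling rate in Hz.
#' @return integer sample offsets relative to time 0 (0 = the onset sample).
#' @keywords internal
ms_to_samples <- function(ms, rate) {
  as.integer(trunc(ms * rate / 1000))
}

assert_finite_matrix <- function(x, what = "features") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("%s contain non-finite values", what), call. = FALSE)
  }
  invisible(x)
}

#' Parse a fraction or decimal string
#'
#' Mixing-matrix configuration files may give proportions as exact rationals
#' ("3/8") or decimals ("0.375"); numbers pass through unchanged.
#'
#' @param x character or numeric vector.
#' @return numeric vector.
#' @keywords internal
parse_fraction <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) {
        stop(sprintf("cannot parse fraction '%s'", s), call. = FALSE)
      }
      as.numeric(parts[1L]) / as.numeric(parts[2L])
    } else {
      as.numeric(s)
    }
  }, numeric(1), USE.NAMES = FALSE)
}
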