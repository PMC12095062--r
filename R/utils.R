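## Internal helpers shared across modules.

#' Evaluate code with a temporary, isolated RNG state
#'
#' Every stochastic operation in the package takes an explicit seed and must
#' not disturb (or depend on) the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## scalar validators; stop with the argument name in the message
check_positive <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  x
}

check_nonneg <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative number", name), call. = FALSE)
  x
}

check_count <- function(x, name = deparse(substitute(x)), min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

## cross product of two 3-vectors
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

unit3 <- function(v) v / sqrt(sum(v^2))

## an orthonormal pair completing unit vector t to a right-handed frame
frame_about <- function(t) {
  a <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(a - sum(a * t) * t)
  list(e1 = e1, e2 = cross3(t, e1))
}
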