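#' @useDynLib wheatsyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded operations do not perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Normalise an angle to [0, 2*pi)
#' @keywords internal
wrap_angle <- function(a) a %% (2 * pi)

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stopf("cannot normalise a near-zero vector")
  v / n
}

#' Rotate a 3D vector about an axis (Rodrigues' formula)
#' @keywords internal
rotate_about <- function(v, axis, theta) {
  u <- unit3(axis)
  v * cos(theta) + pracma_cross(u, v) * sin(theta) +
    u * sum(u * v) * (1 - cos(theta))
}

# plain cross product; avoids pulling in pracma for one primitive
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
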