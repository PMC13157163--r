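# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and one or more indices, kept within
# 32-bit integer range so set.seed() accepts it.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i)) %% 2147483647
  as.integer(s)
}

#' Wrap angles to (-pi, pi]
#'
#' @param theta Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

norm2 <- function(v) sqrt(sum(v * v))
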