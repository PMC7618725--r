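# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Counter-based derivation of per-participant (or per-stage) seeds from a
#' master seed, so that individual participants can be regenerated without
#' re-running the whole cohort. The map is a fixed affine hash modulo the
#' Mersenne prime 2^31 - 1; all arithmetic stays exact in doubles.
#'
#' @param seed master integer seed.
#' @param index non-negative integer counter (participant index, stage id).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, index) {
  stopifnot(is.finite(seed), is.finite(index))
  s <- as.double(seed) %% 2147483647
  x <- (s * 48271 + as.double(index) * 69621 + 12345) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Hann taper of length n (n >= 1).
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Smooth box on [a, b] with raised-cosine ramps of width `ramp` seconds.
ramped_box <- function(t, a, b, ramp) {
  out <- numeric(length(t))
  core <- t >= a + ramp & t <= b - ramp
  out[core] <- 1
  up <- t >= a & t < a + ramp
  out[up] <- 0.5 - 0.5 * cos(pi * (t[up] - a) / ramp)
  dn <- t > b - ramp & t <= b
  out[dn] <- 0.5 - 0.5 * cos(pi * (b - t[dn]) / ramp)
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
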