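# Internal helpers shared across modules.

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Linear interpolation with strict range checking (voltages are strictly
# increasing, so approx() is well defined).
.interpAt <- function(x, y, x0) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least two finite points to interpolate")
  if (x0 < min(x) || x0 > max(x)) {
    stop(sprintf("cannot interpolate at %.3g: outside data range [%.3g, %.3g]",
                 x0, min(x), max(x)))
  }
  stats::approx(x, y, xout = x0, ties = "ordered")$y
}

.stopCondition <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Additive Gaussian noise scaled to the maximum absolute noise-free signal.
.addNoise <- function(y, noiseSD, seed = NULL) {
  stopifnot(is.numeric(noiseSD), length(noiseSD) == 1L, noiseSD >= 0)
  if (noiseSD == 0) return(y)
  sdAbs <- noiseSD * max(abs(y))
  .withSeed(seed, y + stats::rnorm(length(y), mean = 0, sd = sdAbs))
}
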