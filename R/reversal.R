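# Reversal-potential estimation by polynomial root finding.

#' Estimate the reversal potential from an I-V series
#'
#' Fits a polynomial (degree 9 by default) to the I-V relationship and takes
#' as the reversal potential the real root nearest the empirical sign change
#' of the current. Voltages are rescaled to \[-1, 1\] before fitting so the
#' high-degree fit stays well conditioned, and roots are mapped back to mV.
#'
#' Root selection: among real roots inside the data range, roots lying inside
#' the voltage bracket of an empirical sign change are preferred; ties are
#' broken by proximity to the linear-interpolation zero crossing. If the
#' current never changes sign inside the window (strongly rectifying data),
#' an error of class `iglur_no_reversal` is raised.
#'
#' With fewer than `degree + 2` points the degree is reduced to n - 2 and the
#' reduction recorded in the estimate.
#'
#' @param iv an [IVSeries-class].
#' @param degree polynomial degree, default 9.
#' @param window optional `c(vmin, vmax)` restriction (mV).
#' @return A [ReversalEstimate-class].
#' @examples
#' v <- seq(-100, 100, 10)
#' erev(estimateReversal(IVSeries(v, 2 * (v - 10))))  # 10 mV
#' @export
estimateReversal <- function(iv, degree = 9, window = NULL) {
  stopifnot(is(iv, "IVSeries"), degree >= 1)
  v <- iv@voltages
  i <- iv@currents
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- v >= min(window) & v <= max(window)
    v <- v[keep]; i <- i[keep]
  }
  n <- length(v)
  if (n < 4L)
    .stopCondition("iglur_config_error",
                   "reversal estimation needs at least 4 points in the window")
  usedDegree <- as.integer(min(degree, n - 2L))

  # empirical sign change(s)
  s <- sign(i)
  exact <- which(s == 0)
  flips <- which(s[-n] * s[-1] < 0)
  if (length(exact) == 0L && length(flips) == 0L)
    .stopCondition("iglur_no_reversal",
                   "no reversal in range: current does not change sign")
  # linear-interpolation crossing of the first bracket (tie-break anchor)
  z0 <- if (length(exact)) {
    v[exact[1]]
  } else {
    j <- flips[1]
    v[j] + (v[j + 1] - v[j]) * (0 - i[j]) / (i[j + 1] - i[j])
  }

  # conditioning: rescale voltage to [-1, 1]
  mid <- (max(v) + min(v)) / 2
  half <- (max(v) - min(v)) / 2
  x <- (v - mid) / half
  X <- outer(x, 0:usedDegree, `^`)
  cf <- stats::lm.fit(X, i)$coefficients
  cf[!is.finite(cf)] <- 0
  fitted <- drop(X %*% cf)
  rms <- sqrt(mean((fitted - i)^2))

  roots <- polyroot(cf)
  real <- Re(roots[abs(Im(roots)) < 1e-6 * (1 + abs(Re(roots)))])
  cand <- real * half + mid
  cand <- cand[cand >= min(v) & cand <= max(v)]
  if (length(cand) == 0L) {
    # fall back to the interpolation crossing (degenerate fit)
    est <- z0
  } else {
    bracketed <- logical(length(cand))
    for (j in flips) {
      bracketed <- bracketed | (cand >= v[j] & cand <= v[j + 1])
    }
    if (length(exact)) {
      bracketed <- bracketed | vapply(cand, function(cc)
        any(abs(cc - v[exact]) < 1e-9), logical(1))
    }
    pool <- if (any(bracketed)) cand[bracketed] else cand
    est <- pool[which.min(abs(pool - z0))]
  }

  new("ReversalEstimate", erev = est, degree = usedDegree,
      window = range(v), rms = rms, nPoints = as.integer(n))
}
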