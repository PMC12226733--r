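# Independent oracles and fixture builders used across the suite.

# Brute-force bisection root of the GHK current sum: independent of the
# polynomial reversal estimator it is used to check.
ghkBisectionRoot <- function(cond, lower = -150, upper = 150, tol = 1e-7) {
  f <- function(v) ghkCurrent(cond, v)
  fl <- f(lower)
  stopifnot(fl * f(upper) < 0)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (fl * f(mid) <= 0) upper <- mid else {
      lower <- mid
      fl <- f(mid)
    }
  }
  (lower + upper) / 2
}

# Random bi-ionic condition (ambient RNG stream): internal Na against a
# variable external monovalent, sometimes with external Ca2+ added. Built so
# the reversal potential falls well inside the -100..+100 mV grid.
randomGHKCondition <- function() {
  ions <- data.frame(
    name = c("Na_in", "X_out"), charge = 1,
    concIn = c(150, 0),
    concOut = c(0, stats::runif(1, 50, 300)),
    permeability = c(1, stats::runif(1, 0.4, 2.5)))
  if (stats::runif(1) < 0.3) {
    ions <- rbind(ions, data.frame(
      name = "Ca_out", charge = 2, concIn = 0, concOut = 4,
      permeability = stats::runif(1, 0.3, 2)))
  }
  ghkCondition(ions)
}

# Wildtype-like and Q/R/N-glutamine-like blocker truths (block parameters of
# the wildtype and S->Q pore variants used as generating conditions).
wildtypeTruth <- function(spm = 30, vrev = 0) {
  blockerTruth(gmax = 1, g = 10, h = -18.5, L = 1.4, k = 36.5, spm = spm,
               vrev = vrev)
}
qrnGlnTruth <- function(spm = 30) {
  blockerTruth(gmax = 1, g = 5, h = -15.3, L = 0.7, k = 28.3, spm = spm)
}
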