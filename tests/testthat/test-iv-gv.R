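# Reversal estimation, conductance conversion, normalization and the 0 mV
# difference statistic.

test_that("reversal estimation recovers a linear I-V root exactly", {
  v <- seq(-100, 100, 10)
  est <- estimateReversal(IVSeries(v, 2 * (v - 10)))
  expect_equal(erev(est), 10, tolerance = 1e-8)
  expect_identical(est@degree, 9L)
})

test_that("reversal estimation matches the bisection oracle on GHK data", {
  set.seed(20)
  for (rep in 1:20) {
    cond <- randomGHKCondition()
    iv <- simulateIV(cond)
    expect_lt(abs(erev(estimateReversal(iv)) - ghkBisectionRoot(cond)), 0.1)
  }
})

test_that("reversal estimate is scale-invariant and translation-equivariant", {
  set.seed(5)
  for (rep in 1:10) {
    cond <- randomGHKCondition()
    iv <- simulateIV(cond)
    e0 <- erev(estimateReversal(iv))
    # uniform current scaling
    ivScaled <- IVSeries(voltages(iv), 7.3 * currents(iv))
    expect_equal(erev(estimateReversal(ivScaled)), e0, tolerance = 1e-6)
    # voltage translation
    ivShift <- IVSeries(voltages(iv) + 15, currents(iv))
    expect_equal(erev(estimateReversal(ivShift)), e0 + 15, tolerance = 1e-6)
  }
})

test_that("strong rectification without a sign change is refused", {
  v <- seq(-100, 100, 10)
  expect_error(estimateReversal(IVSeries(v, exp(v / 40) + 1)),
               class = "iglur_no_reversal")
})

test_that("polynomial degree is reduced for short series", {
  v <- seq(-30, 30, 10)
  est <- estimateReversal(IVSeries(v, 3 * (v - 5)))
  expect_identical(est@degree, length(v) - 2L)
  expect_equal(erev(est), 5, tolerance = 1e-8)
})

test_that("conductance conversion and reconstruction are exact", {
  v <- seq(-100, 100, 10)
  iv <- IVSeries(v, 5 * v)  # ohmic, 5 nS, Erev = 0
  gv <- computeConductance(iv, erev = 0)
  keep <- !gv@excluded
  expect_equal(conductance(gv)[v == -100], 5)  # -500 pA at -100 mV
  expect_true(all(abs(conductance(gv)[keep] - 5) < 1e-12))
  # excluded voltages are flagged, not dropped
  expect_identical(length(conductance(gv)), length(v))
  expect_true(gv@excluded[v == 0])
  # multiplying back by (V - Erev) reconstructs the currents
  expect_equal(conductance(gv)[keep] * (v[keep] - 0), currents(iv)[keep])
})

test_that("blocker-generated G-V round-trips through the I-V form", {
  sim <- simulateGVBlocker(wildtypeTruth(vrev = 12))
  gv2 <- computeConductance(sim$iv, erev = 12)
  keep <- !gv2@excluded
  expect_equal(conductance(gv2)[keep], conductance(sim$gv)[keep],
               tolerance = 1e-12)
})

test_that("all-excluded conversion errors out", {
  v <- seq(-4, 5, 1)
  expect_error(computeConductance(IVSeries(v, v), erev = 0,
                                  exclusionHalfwidth = 10),
               class = "iglur_config_error")
})

test_that("normalization modes behave and are recorded", {
  sim <- simulateGVBlocker(wildtypeTruth())
  nm <- normalizeGV(sim$gv, "to_max")
  expect_equal(max(conductance(nm), na.rm = TRUE), 1)
  expect_identical(nm@normalization, "to_max")
  expect_gt(nm@referenceValue, 0)

  v <- seq(-100, 100, 10)
  const <- GVSeries(v, rep(4.2, length(v)))
  na <- normalizeGV(const, "to_anchor_voltage", anchor = -100)
  expect_true(all(conductance(na) == 1))
  zero <- GVSeries(v, rep(0, length(v)))
  expect_error(normalizeGV(zero, "to_max"), class = "iglur_config_error")
})

test_that("normalized U-shape minimum sits at the closed-form argmin", {
  v <- seq(-100, 100, 1)
  gv <- simulateGVBlocker(wildtypeTruth(), voltages = v)$gv
  nm <- normalizeGV(gv, "to_max")
  tr <- wildtypeTruth()
  closedForm <- predictG(tr, v)
  expect_equal(v[which.min(conductance(nm))], v[which.min(closedForm)])
})

test_that("conductance difference at 0 mV behaves as specified", {
  v <- seq(-100, 100, 10)
  a <- normalizeGV(GVSeries(v, 2 + v / 200), "to_max")
  expect_equal(conductanceDiffAtZero(a, a), 0)
  # constructed 30% reduction at 0 mV
  b <- GVSeries(v, 0.7 * conductance(a))
  b@normalization <- "to_max"
  expect_equal(conductanceDiffAtZero(b, a),
               -30 * conductance(a)[v == 0] / 1, tolerance = 1e-9)
  expect_error(conductanceDiffAtZero(GVSeries(v, 2 + v / 200), a),
               class = "iglur_config_error")
})

test_that("pore variants with stronger block give a negative 0 mV shift", {
  wt <- normalizeGV(simulateGVBlocker(wildtypeTruth())$gv, "to_max")
  qv <- normalizeGV(simulateGVBlocker(qrnGlnTruth())$gv, "to_max")
  expect_lt(conductanceDiffAtZero(qv, wt), 0)
})
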