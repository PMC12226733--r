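# Single permeant blocker model: closed forms and fitting.

test_that("Kd(V) closed form is exact", {
  expect_equal(kdOfV(10, -18.5, 1.4, 36.5, 0), 11.4)
  # pure relief branch is strictly increasing for k > 0
  v <- seq(-100, 100, 10)
  expect_true(all(diff(kdOfV(0, -20, 1.4, 35, v)) > 0))
  # direct arithmetic check
  expect_equal(kdOfV(10, -20, 1.4, 35, -100),
               10 * exp(5) + 1.4 * exp(-100 / 35))
})

test_that("predicted conductance obeys its closed-form identities", {
  tr <- wildtypeTruth()
  v <- seq(-100, 100, 10)
  expect_equal(predictG(tr, v, spm = 0), rep(1, length(v)))
  # G = Gmax/2 wherever Kd(V) = [Spm]
  vStar <- -20
  spmStar <- kdOfV(tr$g, tr$h, tr$L, tr$k, vStar)
  expect_equal(predictG(tr, vStar, spm = spmStar), tr$gmax / 2)
  # bounded in (0, Gmax]; U-shaped at the wildtype truth
  g <- predictG(tr, v)
  expect_true(all(g > 0 & g <= tr$gmax))
  expect_gt(which.min(g), 1)
  expect_lt(which.min(g), length(v))
})

test_that("doubling spm together with g and L leaves the model invariant", {
  v <- seq(-100, 100, 5)
  a <- predictG(list(gmax = 1, g = 10, h = -18.5, L = 1.4, k = 36.5),
                v, spm = 30)
  b <- predictG(list(gmax = 1, g = 20, h = -18.5, L = 2.8, k = 36.5),
                v, spm = 60)
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("Kd(V) has a unique interior minimum inherited by normalized G", {
  tr <- wildtypeTruth()
  v <- seq(-150, 150, 0.5)
  kd <- kdOfV(tr$g, tr$h, tr$L, tr$k, v)
  iMin <- which.min(kd)
  expect_true(all(diff(kd[1:iMin]) < 0))
  expect_true(all(diff(kd[iMin:length(v)]) > 0))
  expect_equal(v[which.min(predictG(tr, v))], v[iMin], tolerance = 1)
})

test_that("noise-free self-generated G-V is recovered to numerical precision", {
  sim <- simulateGVBlocker(wildtypeTruth())
  fit <- fitBlocker(sim$gv, spm = 30)
  p <- blockerParams(fit)
  truth <- c(gmax = 1, g = 10, h = -18.5, L = 1.4, k = 36.5, kd0 = 11.4)
  for (nm in names(truth)) {
    expect_lt(abs(p[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 1e-3)
  }
  expect_true(fit@diagnostics$converged)
  expect_lt(fit@diagnostics$rms, 1e-8)
  expect_equal(kd0(fit), p[["g"]] + p[["L"]])
})

test_that("the fit window is honored", {
  sim <- simulateGVBlocker(wildtypeTruth())
  fit <- fitBlocker(sim$gv, spm = 30, window = c(-100, 0))
  expect_identical(fit@diagnostics$nPoints, 11L)
  expect_equal(fit@window, c(-100, 0))
  expect_error(fitBlocker(sim$gv, spm = 30, window = c(-100, -80)),
               class = "iglur_config_error")
})

test_that("block-free inputs are refused, not fit", {
  sim <- simulateGVBlocker(wildtypeTruth())
  expect_error(fitBlocker(sim$gv, spm = 0), class = "iglur_block_free")
  flat <- simulateGVBlocker(blockerTruth(spm = 0))$gv
  expect_error(fitBlocker(flat, spm = 30), class = "iglur_block_free")
})

test_that("intrinsic exponential G-V fit recovers its parameters", {
  v <- seq(-100, 100, 10)
  gv <- GVSeries(v, 1 + (0.5 - 1) * exp(v / -63.1))
  fit <- fitIntrinsic(gv)
  expect_equal(fit@g0, 0.5, tolerance = 1e-8)
  expect_equal(fit@vc, -63.1, tolerance = 1e-6)
  expect_lt(fit@diagnostics$rms, 1e-10)
  expect_equal(fit@empiricalMin, min(conductance(gv)))
  # constant conductance: amplitude degenerate, Vc unidentifiable
  cfit <- fitIntrinsic(GVSeries(v, rep(1, length(v))))
  expect_equal(cfit@g0, 1)
  expect_true(is.na(cfit@vc))
  expect_false(cfit@diagnostics$converged)
})
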