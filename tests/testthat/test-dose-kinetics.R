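# Hill, inhibition, biphasic dose-response and recovery fitting.

test_that("Hill fit recovers exact generating parameters", {
  tab <- simulateDoseResponse(0.11, 1.3)
  fit <- fitHill(tab)
  expect_equal(fit@ec50, 0.11, tolerance = 1e-8)
  expect_equal(fit@hillSlope, 1.3, tolerance = 1e-6)
  expect_lt(fit@diagnostics$rms, 1e-10)
  # response at c = EC50 is 0.5 by construction
  expect_equal(simulateDoseResponse(0.11, 1.3, concs = 0.11)@responses, 0.5)
})

test_that("Hill fit is invariant to the concentration unit tag", {
  concs <- 0.11 * 10^seq(-1.5, 1.5, length.out = 8)
  y <- 1 / (1 + (0.11 / concs)^1.3)
  fitMM <- fitHill(doseTable(concs, y, unit = "mM"))
  fitUM <- fitHill(doseTable(concs * 1000, y, unit = "uM"))
  expect_equal(fitUM@ec50, 1000 * fitMM@ec50, tolerance = 1e-8)
  expect_identical(fitUM@unit, "uM")
  expect_equal(fitUM@hillSlope, fitMM@hillSlope, tolerance = 1e-8)
})

test_that("inhibition fit recovers the IC50 and flags flat data", {
  concs <- 50 * 10^seq(-2, 2, length.out = 9)
  y <- 1 - 1 / (1 + (50 / concs)^1.1)
  fit <- fitInhibition(doseTable(concs, y, direction = "inhibition",
                                 unit = "uM"))
  expect_equal(fit@ec50, 50, tolerance = 1e-8)
  # at c = IC50 the blocked response is 0.5
  expect_equal(y[abs(concs - 50) < 1e-9], 0.5)
  flat <- fitInhibition(doseTable(concs, rep(1, 9),
                                  direction = "inhibition", unit = "uM"))
  expect_false(flat@diagnostics$converged)
  expect_true(is.na(flat@ec50))
})

test_that("biphasic fit recovers both midpoints on noise-free data", {
  concs <- 10^seq(-2, 3, length.out = 12)
  y <- predictBiphasic(concs, 0.2, 1.0, 1.2, 7.7, 1.1)
  fit <- fitBiphasic(doseTable(concs, y, unit = "uM"))
  expect_lt(abs(fit@ec50Stim - 1.0) / 1.0, 0.01)
  expect_lt(abs(fit@ic50Inhib - 7.7) / 7.7, 0.01)
  expect_lt(abs(fit@stimAmplitude - 0.2) / 0.2, 0.01)
  # potentiation pushes the intermediate response above 1
  expect_gt(max(y), 1)
})

test_that("biphasic fit nests the pure-inhibition model", {
  concs <- 10^seq(-2, 3, length.out = 12)
  y <- predictBiphasic(concs, 0, 1, 1, 7.7, 1.1)
  # degenerate single-phase data fall back to the monophasic fit, with a
  # warning when the full biphasic optimization cannot converge
  bi <- withCallingHandlers(
    fitBiphasic(doseTable(concs, y, unit = "uM")),
    warning = function(w) {
      expect_match(conditionMessage(w), "falling back")
      invokeRestart("muffleWarning")
    })
  mono <- fitInhibition(doseTable(concs, y, direction = "inhibition",
                                  unit = "uM"))
  expect_lt(abs(bi@ic50Inhib - mono@ec50) / mono@ec50, 0.01)
  expect_lt(bi@stimAmplitude, 0.01)
})

test_that("recovery fit recovers tau and flags degenerate series", {
  r <- simulateRecovery(184, amplitude = -0.9)
  fit <- fitRecovery(r$interval_ms, r$ratio)
  expect_equal(fit@tau, 184, tolerance = 1e-6)
  expect_equal(fit@amplitude, -0.9, tolerance = 1e-6)
  expect_lt(fit@diagnostics$rms, 1e-10)
  # y(0) = 1 + A
  r0 <- simulateRecovery(184, intervals = c(1e-12, 100, 200, 400),
                         amplitude = -0.6)
  expect_equal(r0$ratio[1], 0.4, tolerance = 1e-9)
  # fully recovered series: A ~ 0, tau unidentifiable
  flat <- fitRecovery(c(50, 100, 500, 1000), rep(1, 4))
  expect_false(flat@diagnostics$tauIdentifiable)
  expect_true(is.na(flat@tau))
})

test_that("fitter preconditions are enforced", {
  expect_error(fitHill(doseTable(c(1, 2, 3), c(0.1, 0.5, 0.9))),
               class = "iglur_config_error")
  expect_error(
    fitHill(doseTable(1:8, rep(0.5, 8), direction = "inhibition")),
    class = "iglur_config_error")
  expect_error(fitRecovery(c(10, 20, 30), c(0.2, 0.5, 0.9)),
               class = "iglur_config_error")
  expect_error(fitRecovery(c(10, 20, 30, 40), c(0.2, 0.5, 0.9, 1.5)),
               class = "iglur_config_error")
})
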