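# Seeded generators: determinism, noise-free closed forms, and ground-truth
# recoverability.

test_that("generators are bit-identical under identical seed and parameters", {
  cond <- ghkCondition(data.frame(name = c("Na", "K"), charge = 1,
                                  concIn = c(150, 0), concOut = c(0, 150),
                                  permeability = c(1, 1.2)))
  expect_identical(currents(simulateIV(cond, noiseSD = 0.05, seed = 42)),
                   currents(simulateIV(cond, noiseSD = 0.05, seed = 42)))
  expect_false(identical(currents(simulateIV(cond, noiseSD = 0.05, seed = 42)),
                         currents(simulateIV(cond, noiseSD = 0.05, seed = 43))))
  s1 <- simulateGVBlocker(wildtypeTruth(), noiseSD = 0.05, seed = 7)
  s2 <- simulateGVBlocker(wildtypeTruth(), noiseSD = 0.05, seed = 7)
  expect_identical(conductance(s1$gv), conductance(s2$gv))
  r1 <- simulateRecovery(184, noiseSD = 0.05, seed = 3)
  r2 <- simulateRecovery(184, noiseSD = 0.05, seed = 3)
  expect_identical(r1$ratio, r2$ratio)
  f1 <- simulateAlignmentFixture(c("653" = "S"), mutationRate = 0.05,
                                 seed = 11)
  f2 <- simulateAlignmentFixture(c("653" = "S"), mutationRate = 0.05,
                                 seed = 11)
  expect_identical(as.character(f1), as.character(f2))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateIV(
    ghkCondition(data.frame(name = "Na", charge = 1, concIn = 150,
                            concOut = 150, permeability = 1)),
    noiseSD = 0.05, seed = 9))
  expect_identical(before, .Random.seed)
})

test_that("GHK bi-ionic currents cross zero where symmetry demands", {
  symNa <- ghkCondition(data.frame(name = "Na", charge = 1, concIn = 150,
                                   concOut = 150, permeability = 1))
  expect_equal(ghkCurrent(symNa, 0), 0, tolerance = 1e-12)
  # equal-permeability Na_in / K_out also reverses at 0 mV
  naK <- ghkCondition(data.frame(name = c("Na", "K"), charge = 1,
                                 concIn = c(150, 0), concOut = c(0, 150),
                                 permeability = c(1, 1)))
  expect_lt(abs(ghkBisectionRoot(naK)), 1e-6)
  iv <- simulateIV(naK)
  expect_lt(abs(erev(estimateReversal(iv))), 0.1)
})

test_that("divalent GHK zero crossing matches the bisection oracle", {
  kCa <- ghkCondition(data.frame(
    name = c("K_in", "Ca_out"), charge = c(1, 2),
    concIn = c(100, 0), concOut = c(0, 4), permeability = c(1, 0.67)))
  root <- ghkBisectionRoot(kCa)
  iv <- simulateIV(kCa)
  expect_lt(abs(erev(estimateReversal(iv)) - root), 1)
})

test_that("blocker G-V generator matches its closed form", {
  v <- seq(-100, 100, 10)
  noBlock <- blockerTruth(spm = 0)
  expect_equal(conductance(simulateGVBlocker(noBlock, v)$gv),
               rep(noBlock$gmax, length(v)))
  # Kd(0) = g + L, so spm = g + L halves the conductance at 0 mV
  tr <- blockerTruth(g = 8, L = 3.4, spm = 8 + 3.4)
  gv <- simulateGVBlocker(tr, v)$gv
  expect_equal(conductance(gv)[v == 0], tr$gmax / 2, tolerance = 1e-12)
  # wildtype-like truth: interior minimum with relief at depolarized V
  gWT <- conductance(simulateGVBlocker(wildtypeTruth(), v)$gv)
  iMin <- which.min(gWT)
  expect_gt(iMin, 1)
  expect_lt(iMin, length(v))
  expect_gt(gWT[length(v)], gWT[iMin])
  # derived I-V obeys I = G (V - vrev)
  sim <- simulateGVBlocker(wildtypeTruth(), v)
  expect_equal(currents(sim$iv), conductance(sim$gv) * v)
})

test_that("dose-response generator follows the Hill closed form", {
  tab <- simulateDoseResponse(0.11, 1.5, concs = 0.11)
  expect_equal(tab@responses, 0.5)
  expect_equal(simulateDoseResponse(0.11, 1.5, concs = 1e6)@responses, 1,
               tolerance = 1e-6)
  # generating-truth recovery at 5% noise, 8 log-spaced concentrations
  # (tolerance calibrated by repeated-seed simulation, so assert the median)
  set.seed(10)
  errs <- replicate(11, {
    tab <- simulateDoseResponse(0.11, 1.5, noiseSD = 0.05)
    abs(fitHill(tab)@ec50 - 0.11) / 0.11
  })
  expect_lt(median(errs), 0.10)
})

test_that("recovery generator follows its exponential closed form", {
  r <- simulateRecovery(184, intervals = c(1e-9, 50, 500, 5000),
                        amplitude = -1)
  expect_equal(r$ratio[1], 0, tolerance = 1e-9)
  expect_equal(r$ratio[4], 1, tolerance = 0.05)
  set.seed(10)
  errs <- replicate(11, {
    r <- simulateRecovery(184, noiseSD = 0.05)
    abs(fitRecovery(r$interval_ms, r$ratio)@tau - 184) / 184
  })
  expect_lt(median(errs), 0.15)
})

test_that("generator preconditions are enforced", {
  expect_error(ghkCondition(data.frame()), class = "iglur_config_error")
  expect_error(
    ghkCondition(data.frame(name = "Na", charge = 1, concIn = -1,
                            concOut = 150, permeability = 1)),
    class = "iglur_config_error")
  expect_error(blockerTruth(spm = -1), class = "iglur_config_error")
  expect_error(blockerTruth(h = 5), class = "iglur_config_error")
  expect_error(simulateDoseResponse(0.11, concs = c(-1, 1)),
               class = "iglur_config_error")
  expect_error(simulateRecovery(-5), class = "iglur_config_error")
  expect_error(simulateGVBlocker(wildtypeTruth(), voltages = c(-300, 0, 100)),
               class = "iglur_config_error")
})

test_that("alignment fixture round-trips planted residues", {
  fx <- simulateAlignmentFixture(c("653" = "S", "655" = "I", "732" = "F"))
  m <- mapToReference(fx[[2]])
  prof <- extractSites(m, fx[[2]])
  expect_identical(unname(prof@sites[c("653", "655", "732")]),
                   c("S", "I", "F"))
  # epsilon-receptor-like pore: serine Q/R/N with the +4 aspartate retained
  fx2 <- simulateAlignmentFixture(c("607" = "S"))
  prof2 <- extractSites(mapToReference(fx2[[2]]), fx2[[2]])
  expect_identical(prof2@qrn, "S")
  expect_identical(prof2@plus4, "D")
  # deletion at a site reports a gap and an unpredictable call
  fx3 <- simulateAlignmentFixture(c("653" = "-"))
  prof3 <- extractSites(mapToReference(fx3[[2]]), fx3[[2]])
  expect_identical(unname(prof3@sites["653"]), "-")
  expect_identical(predictLigand(prof3)@label, "unpredictable")
  expect_error(simulateAlignmentFixture(c("9999" = "S")),
               class = "iglur_config_error")
})
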