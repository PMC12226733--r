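# Seeded synthetic-data generators. Every generator has a closed-form
# noise-free backbone plus additive Gaussian noise scaled to the maximum
# absolute signal, and records its ground truth in the output metadata so
# parameter recovery can be tested.

#' Ground-truth parameters for the single permeant blocker generator
#'
#' Defaults follow the wildtype epsilon-receptor condition: Kd(0 mV) =
#' g + L = 11.4 µM (split 10:1.4 between the block and permeation branches),
#' h = -18.5 mV, k = 36.5 mV, internal spermine 30 µM, unit maximal
#' conductance and a 0 mV reversal potential.
#'
#' @param gmax maximal conductance (> 0).
#' @param g,L µM branch amplitudes at 0 mV (>= 0).
#' @param h voltage dependence of block onset (mV, < 0).
#' @param k voltage dependence of block relief (mV, > 0).
#' @param spm internal spermine concentration (µM, >= 0).
#' @param vrev reversal potential (mV) used when deriving currents.
#' @return named list of class `"BlockerTruth"`.
#' @export
blockerTruth <- function(gmax = 1, g = 10, h = -18.5, L = 1.4, k = 36.5,
                         spm = 30, vrev = 0) {
  if (gmax <= 0) .stopCondition("iglur_config_error", "gmax must be > 0")
  if (g < 0 || L < 0) .stopCondition("iglur_config_error", "g, L must be >= 0")
  if (h >= 0) .stopCondition("iglur_config_error", "h must be negative")
  if (k <= 0) .stopCondition("iglur_config_error", "k must be positive")
  if (spm < 0) .stopCondition("iglur_config_error", "spm must be >= 0")
  structure(list(gmax = gmax, g = g, h = h, L = L, k = k, spm = spm,
                 vrev = vrev),
            class = c("BlockerTruth", "list"))
}

#' Simulate a GHK-shaped bi-ionic I-V series
#'
#' Currents follow the Goldman-Hodgkin-Katz flux equation summed over the
#' ions in `cond` (see [ghkCurrent()]), with seeded additive Gaussian noise
#' scaled to the maximum absolute noise-free current.
#'
#' @param cond a [ghkCondition()].
#' @param voltages mV, strictly increasing; default -100..100 in 10 mV steps.
#' @param noiseSD additive noise as a fraction of the maximum absolute
#'   current (>= 0).
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical output.
#' @param gain patch gain passed to [ghkCurrent()].
#' @return An [IVSeries-class]; the generating condition and noise settings
#'   are stored in its `condition` metadata.
#' @export
simulateIV <- function(cond, voltages = seq(-100, 100, 10), noiseSD = 0,
                       seed = NULL, gain = 1e-5) {
  if (length(voltages) == 0L || any(diff(voltages) <= 0))
    .stopCondition("iglur_config_error",
                   "voltages must be non-empty and strictly increasing")
  i0 <- ghkCurrent(cond, voltages, gain = gain)
  i <- .addNoise(i0, noiseSD, seed)
  IVSeries(voltages, i,
           condition = list(generator = "ghk", truth = cond,
                            noiseSD = noiseSD, seed = seed, gain = gain))
}

#' Simulate a G-V family shaped by the single permeant blocker model
#'
#' G(V) = gmax / (1 + spm / Kd(V)) with Kd(V) = g e^(V/h) + L e^(V/k), plus
#' additive noise; the matching I-V series is derived as
#' I = G (V - vrev).
#'
#' @param truth a [blockerTruth()] parameter set.
#' @param voltages mV within ±200, default -100..100 in 10 mV steps.
#' @param noiseSD additive noise fraction applied to the conductance.
#' @param seed integer seed.
#' @return list with elements `gv` ([GVSeries-class]), `iv`
#'   ([IVSeries-class]) and `truth`.
#' @export
simulateGVBlocker <- function(truth, voltages = seq(-100, 100, 10),
                              noiseSD = 0, seed = NULL) {
  stopifnot(inherits(truth, "BlockerTruth"))
  if (any(abs(voltages) > 200))
    .stopCondition("iglur_config_error", "voltages must be within ±200 mV")
  if (any(diff(voltages) <= 0))
    .stopCondition("iglur_config_error", "voltages must be strictly increasing")
  g0 <- predictG(truth, voltages)
  g <- .addNoise(g0, noiseSD, seed)
  meta <- list(generator = "blocker", truth = truth, noiseSD = noiseSD,
               seed = seed)
  gv <- GVSeries(voltages, g, vrevUsed = truth$vrev,
                 excluded = rep(FALSE, length(voltages)), condition = meta)
  iv <- IVSeries(voltages, g * (voltages - truth$vrev), condition = meta)
  list(gv = gv, iv = iv, truth = truth)
}

#' Simulate a Hill-shaped dose-response table
#'
#' Normalized responses y = 1 / (1 + (EC50/c)^p) plus additive noise.
#'
#' @param ec50 midpoint concentration (> 0, in `unit`).
#' @param hillSlope Hill slope p.
#' @param concs concentrations (> 0); default 8 log-spaced points spanning
#'   two decades around the EC50.
#' @param noiseSD additive noise fraction.
#' @param seed integer seed.
#' @param unit concentration unit tag, default `"mM"`.
#' @param ligand ligand name for the table.
#' @return A [DoseTable-class] (direction `"activation"`).
#' @export
simulateDoseResponse <- function(ec50, hillSlope = 1.5, concs = NULL,
                                 noiseSD = 0, seed = NULL, unit = "mM",
                                 ligand = "ligand") {
  if (ec50 <= 0) .stopCondition("iglur_config_error", "ec50 must be > 0")
  if (is.null(concs))
    concs <- ec50 * 10^seq(-1.5, 1.5, length.out = 8)
  if (any(concs <= 0))
    .stopCondition("iglur_config_error", "concentrations must be > 0")
  y0 <- 1 / (1 + (ec50 / concs)^hillSlope)
  y <- .addNoise(y0, noiseSD, seed)
  tab <- doseTable(concs, y, ligand = ligand, direction = "activation",
                   unit = unit)
  attr(tab, "truth") <- list(ec50 = ec50, hillSlope = hillSlope,
                             noiseSD = noiseSD, seed = seed)
  tab
}

#' Simulate a paired-pulse recovery-from-desensitization series
#'
#' ratio(x) = 1 + A e^(-x/tau) with A in \[-1, 0\]: the test-pulse current
#' recovers exponentially toward the pre-pulse amplitude as the interpulse
#' interval grows.
#'
#' @param tau recovery time constant (ms, > 0).
#' @param intervals interpulse intervals (ms); default 10 log-spaced values
#'   spanning 50-2000 ms.
#' @param amplitude A, in \[-1, 0\]; default -0.9 (deep desensitization).
#' @param noiseSD additive noise fraction.
#' @param seed integer seed.
#' @return data.frame with columns `interval_ms` and `ratio`, plus a
#'   `"truth"` attribute.
#' @export
simulateRecovery <- function(tau, intervals = NULL, amplitude = -0.9,
                             noiseSD = 0, seed = NULL) {
  if (tau <= 0) .stopCondition("iglur_config_error", "tau must be > 0")
  if (amplitude < -1 || amplitude > 0)
    .stopCondition("iglur_config_error", "amplitude must be in [-1, 0]")
  if (is.null(intervals))
    intervals <- 10^seq(log10(50), log10(2000), length.out = 10)
  y0 <- 1 + amplitude * exp(-intervals / tau)
  y <- .addNoise(y0, noiseSD, seed)
  out <- data.frame(interval_ms = intervals, ratio = y)
  attr(out, "truth") <- list(tau = tau, amplitude = amplitude,
                             noiseSD = noiseSD, seed = seed)
  out
}

#' Build an alignment fixture with planted residues
#'
#' Returns a two-sequence set (bundled mature GluA2-numbered reference plus a
#' derived query) in which the query carries the requested residues at
#' GluA2-numbered positions. The value `"-"` plants a deletion (alignment
#' gap) at that position. Optional background mutations (never touching the
#' annotated sites) and an N-terminal truncation exercise non-trivial
#' alignments.
#'
#' @param siteSpec named character vector, names = GluA2 positions, values =
#'   single residue letters or `"-"`.
#' @param mutationRate per-residue probability of a background substitution
#'   away from annotated sites (default 0).
#' @param truncateN number of leading reference residues absent from the
#'   query (default 0).
#' @param seed integer seed for the background mutations.
#' @param queryId name given to the query sequence.
#' @return A `Biostrings::AAStringSet` of length 2 (reference, query).
#' @export
simulateAlignmentFixture <- function(siteSpec, mutationRate = 0,
                                     truncateN = 0, seed = NULL,
                                     queryId = "query") {
  ref <- glua2Reference()
  refChars <- strsplit(as.character(ref), "")[[1]]
  n <- length(refChars)
  pos <- as.integer(names(siteSpec))
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > n))
    .stopCondition("iglur_config_error",
                   "siteSpec positions must lie inside the reference")
  bad <- nchar(siteSpec) != 1L | !grepl("^[A-Z*-]$", siteSpec)
  if (any(bad))
    .stopCondition("iglur_config_error",
                   "siteSpec values must be single residue letters or '-'")

  qChars <- refChars
  qChars[pos] <- unname(siteSpec)

  if (mutationRate > 0) {
    sites <- referenceSites()
    protected <- unique(c(pos, sites$backbone, sites$sidechain, sites$qrn,
                          sites$qrn + sites$plus4Offset,
                          seq(sites$m3[1], sites$m3[2]), sites$siteG))
    .withSeed(seed, {
      hit <- which(stats::runif(n) < mutationRate)
      hit <- setdiff(hit, protected)
      if (length(hit)) {
        aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
        qChars[hit] <- vapply(qChars[hit], function(cur)
          sample(setdiff(aa, cur), 1L), character(1))
      }
    })
  }
  if (truncateN > 0) qChars <- qChars[-seq_len(truncateN)]
  qChars <- qChars[qChars != "-"]

  out <- Biostrings::AAStringSet(c(as.character(ref),
                                   paste(qChars, collapse = "")))
  names(out) <- c("GluA2_synthetic_reference", queryId)
  out
}
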