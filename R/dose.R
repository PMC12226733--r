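# Dose-response (monophasic Hill, inhibition, biphasic) and
# recovery-from-desensitization fitting.

# Split off zero-concentration control rows (carried as y = 1 anchors, not
# log-transformed) and return the fittable part.
.doseData <- function(table) {
  c0 <- table@concentrations == 0
  list(conc = table@concentrations[!c0], y = table@responses[!c0])
}

.hillControl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)

#' Fit a monophasic Hill dose-response curve
#'
#' Least squares of y = 1 / (1 + 10^((log10(EC50) - x) p)) on the
#' log10-concentration axis x, where p is the Hill slope. At c = EC50 the
#' response is 0.5 by construction.
#'
#' @param table a [DoseTable-class] with `direction = "activation"` and at
#'   least 4 nonzero-concentration points.
#' @return A [HillFit-class]; `ec50` is reported in the table's unit.
#' @examples
#' tab <- simulateDoseResponse(0.11, 1.3)
#' fitHill(tab)
#' @export
fitHill <- function(table) {
  stopifnot(is(table, "DoseTable"))
  if (table@direction != "activation")
    .stopCondition("iglur_config_error",
                   "fitHill expects activation data; use fitInhibition")
  d <- .doseData(table)
  if (length(d$conc) < 4L)
    .stopCondition("iglur_config_error", "need at least 4 points to fit")
  df <- data.frame(x = log10(d$conc), y = d$y)
  lx0Start <- df$x[which.min(abs(df$y - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + 10^((lx0 - x) * p)), data = df,
                      start = list(lx0 = lx0Start, p = 1),
                      lower = c(lx0 = min(df$x) - 3, p = 0.05),
                      upper = c(lx0 = max(df$x) + 3, p = 20),
                      control = .hillControl),
    error = function(e) e)
  if (inherits(fit, "error"))
    .stopCondition("iglur_fit_error",
                   paste("Hill fit did not converge:", conditionMessage(fit)))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  new("HillFit", ec50 = 10^unname(cf["lx0"]), hillSlope = unname(cf["p"]),
      direction = "activation", unit = table@unit,
      diagnostics = list(rms = sqrt(mean(res^2)),
                         converged = isTRUE(fit$convInfo$isConv),
                         nPoints = nrow(df)))
}

#' Fit a monophasic inhibition dose-response curve (IC50)
#'
#' Fits y = 1 - Hill(c), i.e. the blocked-current curve, and reports the
#' IC50. Flat responses (no detectable block) are returned with a
#' non-convergence flag and `ec50 = NA` rather than a spurious estimate.
#'
#' @param table a [DoseTable-class] with `direction = "inhibition"`.
#' @return A [HillFit-class] with `direction = "inhibition"`.
#' @export
fitInhibition <- function(table) {
  stopifnot(is(table, "DoseTable"))
  if (table@direction != "inhibition")
    .stopCondition("iglur_config_error",
                   "fitInhibition expects inhibition data")
  d <- .doseData(table)
  if (length(d$conc) < 4L)
    .stopCondition("iglur_config_error", "need at least 4 points to fit")
  if (diff(range(d$y)) < 0.02) {
    return(new("HillFit", ec50 = NA_real_, hillSlope = NA_real_,
               direction = "inhibition", unit = table@unit,
               diagnostics = list(rms = stats::sd(d$y), converged = FALSE,
                                  note = "flat response: no block detectable")))
  }
  df <- data.frame(x = log10(d$conc), y = d$y)
  lx0Start <- df$x[which.min(abs(df$y - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - 1 / (1 + 10^((lx0 - x) * p)), data = df,
                      start = list(lx0 = lx0Start, p = 1),
                      lower = c(lx0 = min(df$x) - 3, p = 0.05),
                      upper = c(lx0 = max(df$x) + 3, p = 20),
                      control = .hillControl),
    error = function(e) e)
  if (inherits(fit, "error"))
    .stopCondition("iglur_fit_error",
                   paste("inhibition fit did not converge:",
                         conditionMessage(fit)))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  new("HillFit", ec50 = 10^unname(cf["lx0"]), hillSlope = unname(cf["p"]),
      direction = "inhibition", unit = table@unit,
      diagnostics = list(rms = sqrt(mean(res^2)),
                         converged = isTRUE(fit$convInfo$isConv),
                         nPoints = nrow(df)))
}

#' Evaluate the biphasic dose-response model
#'
#' y(c) = (1 + a c^ns / (EC50s^ns + c^ns)) (1 - c^ni / (IC50i^ni + c^ni)):
#' one stimulatory Hill phase multiplied by one inhibitory Hill phase. With
#' a > 0 the response transiently exceeds 1 at intermediate concentrations.
#'
#' @param conc concentrations.
#' @param stimAmplitude a (>= 0).
#' @param ec50Stim,slopeStim stimulatory midpoint and slope.
#' @param ic50Inhib,slopeInhib inhibitory midpoint and slope.
#' @return predicted normalized responses.
#' @export
predictBiphasic <- function(conc, stimAmplitude, ec50Stim, slopeStim,
                            ic50Inhib, slopeInhib) {
  stim <- 1 + stimAmplitude * conc^slopeStim /
    (ec50Stim^slopeStim + conc^slopeStim)
  inhib <- 1 - conc^slopeInhib / (ic50Inhib^slopeInhib + conc^slopeInhib)
  stim * inhib
}

#' Fit a biphasic (stimulatory + inhibitory) dose-response curve
#'
#' Fits [predictBiphasic()] by bounded least squares with midpoints in log
#' space. When the stimulatory phase is degenerate (fitted amplitude ~ 0 or
#' non-convergence), falls back to the monophasic inhibition fit with a
#' warning, reporting `stimAmplitude = 0`.
#'
#' @param table a [DoseTable-class] spanning both phases (>= 6 points).
#' @return A [BiphasicFit-class].
#' @export
fitBiphasic <- function(table) {
  stopifnot(is(table, "DoseTable"))
  d <- .doseData(table)
  if (length(d$conc) < 6L)
    .stopCondition("iglur_config_error",
                   "biphasic fit needs at least 6 points")
  df <- data.frame(conc = d$conc, y = d$y)
  lx <- log10(df$conc)
  aStart <- max(max(df$y) - 1, 0.05)
  esStart <- df$conc[which.max(df$y)]
  iiStart <- df$conc[which.min(abs(df$y - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (1 + a * conc^ns / ((10^les)^ns + conc^ns)) *
        (1 - conc^ni / ((10^lii)^ni + conc^ni)),
      data = df,
      start = list(a = aStart, les = log10(esStart), ns = 1,
                   lii = log10(iiStart), ni = 1),
      lower = c(a = 0, les = min(lx) - 3, ns = 0.3, lii = min(lx) - 3,
                ni = 0.3),
      upper = c(a = 10, les = max(lx) + 3, ns = 6, lii = max(lx) + 3,
                ni = 6),
      control = .hillControl),
    error = function(e) e)

  fallback <- inherits(fit, "error")
  if (!fallback) {
    cf <- stats::coef(fit)
    fallback <- !isTRUE(fit$convInfo$isConv)
  }
  if (fallback || stats::coef(fit)[["a"]] < 1e-3) {
    if (fallback)
      warning("biphasic fit degenerate; falling back to monophasic inhibition")
    inhTab <- doseTable(table@concentrations, table@responses,
                        ligand = table@ligand, direction = "inhibition",
                        unit = table@unit)
    inh <- fitInhibition(inhTab)
    return(new("BiphasicFit", stimAmplitude = 0, ec50Stim = NA_real_,
               slopeStim = NA_real_, ic50Inhib = inh@ec50,
               slopeInhib = inh@hillSlope, unit = table@unit,
               diagnostics = c(inh@diagnostics, list(fallback = TRUE))))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  new("BiphasicFit", stimAmplitude = unname(cf["a"]),
      ec50Stim = 10^unname(cf["les"]), slopeStim = unname(cf["ns"]),
      ic50Inhib = 10^unname(cf["lii"]), slopeInhib = unname(cf["ni"]),
      unit = table@unit,
      diagnostics = list(rms = sqrt(mean(res^2)),
                         converged = isTRUE(fit$convInfo$isConv),
                         fallback = FALSE, nPoints = nrow(df)))
}

#' Fit single-exponential recovery from desensitization
#'
#' y(x) = 1 + A e^(-x/tau): the ratio of test-pulse to pre-pulse peak current
#' as a function of the interpulse interval x, rising from 1 + A at x = 0
#' toward 1. A fully recovered (flat) series leaves tau unidentifiable and is
#' flagged rather than fit.
#'
#' @param intervals interpulse intervals (ms, >= 4 values).
#' @param ratios normalized test/pre-pulse ratios (expected within
#'   (-0.1, 1.2)).
#' @return A [RecoveryFit-class].
#' @examples
#' rec <- simulateRecovery(184)
#' fitRecovery(rec$interval_ms, rec$ratio)
#' @export
fitRecovery <- function(intervals, ratios) {
  stopifnot(length(intervals) == length(ratios))
  if (length(intervals) < 4L)
    .stopCondition("iglur_config_error", "need at least 4 intervals")
  if (any(ratios <= -0.1) || any(ratios >= 1.2))
    .stopCondition("iglur_config_error",
                   "recovery ratios outside the plausible (-0.1, 1.2) band")
  if (diff(range(ratios)) < 0.02) {
    return(new("RecoveryFit", amplitude = 0, tau = NA_real_,
               diagnostics = list(rms = stats::sd(ratios), converged = FALSE,
                                  tauIdentifiable = FALSE)))
  }
  df <- data.frame(x = intervals, y = ratios)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 + A * exp(-x / tau), data = df,
                      start = list(A = max(min(min(df$y) - 1, 0), -0.99),
                                   tau = stats::median(df$x)),
                      lower = c(A = -1.5, tau = 1e-3),
                      upper = c(A = 0.2, tau = 1e6),
                      control = .hillControl),
    error = function(e) e)
  if (inherits(fit, "error"))
    .stopCondition("iglur_fit_error",
                   paste("recovery fit did not converge:",
                         conditionMessage(fit)))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  new("RecoveryFit", amplitude = unname(cf["A"]), tau = unname(cf["tau"]),
      diagnostics = list(rms = sqrt(mean(res^2)),
                         converged = isTRUE(fit$convInfo$isConv),
                         tauIdentifiable = abs(unname(cf["A"])) >= 0.02))
}
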