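# Bi-ionic relative permeability ratios from reversal potentials.

#' Monovalent/monovalent bi-ionic permeability ratio
#'
#' pX/pNa = exp(F (Erev_X - Erev_Na) / RT) for a test monovalent cation X
#' outside against the internal reference monovalent (Na), computed from the
#' two reversal potentials.
#'
#' @param erevX reversal potential (mV) under the X condition.
#' @param erevNa reversal potential (mV) under the reference (symmetric Na)
#'   condition.
#' @param temperatureK absolute temperature (K), default 294.
#' @param condition optional metadata list echoed into the result.
#' @return A [PermeabilityResult-class].
#' @examples
#' monovalentRatio(0, 0)                 # ratio 1
#' monovalentRatio(25.335, 0)            # about e
#' @export
monovalentRatio <- function(erevX, erevNa, temperatureK = 294,
                            condition = list()) {
  stopifnot(is.finite(erevX), is.finite(erevNa))
  pc <- physicalConstants(temperatureK)
  ratio <- exp(((erevX - erevNa) / 1000) / pc$rtOverF)
  new("PermeabilityResult", ratio = ratio,
      kind = "monovalent_over_monovalent",
      erevInputs = c(erevX = erevX, erevNa = erevNa),
      condition = c(condition, list(temperatureK = temperatureK)))
}

#' Divalent/monovalent bi-ionic permeability ratio
#'
#' Computes pCa/pX from the reversal potential under a bi-ionic condition
#' with a monovalent cation X inside and Ca2+ outside, using the Lewis form
#'
#' pCa/pX = (\[X\]_in / (4 \[Ca\]_out)) e^(Erev F/RT) (1 + e^(Erev F/RT)).
#'
#' With `asPrinted = TRUE` the trailing factor is replaced by
#' (e^(Erev F/RT) - 1); that variant yields negative ratios for negative
#' reversal potentials and is retained for auditing only.
#'
#' @param erev reversal potential (mV).
#' @param xInmM internal monovalent cation concentration (mM, > 0).
#' @param caOutmM external Ca2+ concentration (mM, > 0).
#' @param temperatureK absolute temperature (K), default 294.
#' @param asPrinted use the (e - 1) trailing factor instead of (1 + e).
#' @param condition optional metadata list echoed into the result.
#' @return A [PermeabilityResult-class].
#' @examples
#' divalentRatio(-59.2, 100, 4)  # about 0.66
#' divalentRatio(-46.9, 100, 4)  # about 1.14
#' @export
divalentRatio <- function(erev, xInmM, caOutmM, temperatureK = 294,
                          asPrinted = FALSE, condition = list()) {
  stopifnot(is.finite(erev))
  if (xInmM <= 0 || caOutmM <= 0)
    .stopCondition("iglur_config_error",
                   "internal monovalent and external Ca2+ must be > 0 mM")
  pc <- physicalConstants(temperatureK)
  e <- exp((erev / 1000) / pc$rtOverF)
  trailing <- if (asPrinted) (e - 1) else (1 + e)
  ratio <- (xInmM / (4 * caOutmM)) * e * trailing
  new("PermeabilityResult", ratio = ratio,
      kind = "divalent_over_monovalent",
      erevInputs = c(erev = erev),
      condition = c(condition,
                    list(xInmM = xInmM, caOutmM = caOutmM,
                         temperatureK = temperatureK,
                         asPrinted = asPrinted)))
}
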