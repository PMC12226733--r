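#' Physical constants used throughout
#'
#' Faraday's constant F = 96485.33 C/mol, gas constant
#' R = 8.314463 J/(K mol), and the ambient temperature (default 294 K).
#'
#' @param temperatureK absolute temperature in K (> 0), default 294.
#' @return list with elements `F` (C/mol), `R` (J K^-1 mol^-1), `T` (K) and
#'   `rtOverF` (thermal voltage RT/F in volts).
#' @examples
#' physicalConstants()$rtOverF * 1000  # about 25.33 mV at 294 K
#' @export
physicalConstants <- function(temperatureK = 294) {
  stopifnot(is.numeric(temperatureK), length(temperatureK) == 1L,
            temperatureK > 0)
  Fc <- 96485.33
  Rg <- 8.314463
  list(F = Fc, R = Rg, T = temperatureK, rtOverF = Rg * temperatureK / Fc)
}

#' Describe a set of ionic conditions for GHK current simulation
#'
#' One row per permeant ion, with charge (+1 or +2), internal and external
#' concentrations (mM) and relative permeability. Used as the generative model
#' for bi-ionic I-V families.
#'
#' @param ions data.frame with columns `name`, `charge`, `concIn`, `concOut`,
#'   `permeability`.
#' @param temperatureK absolute temperature (K), default 294.
#' @return list of class `"GHKCondition"`.
#' @examples
#' ghkCondition(data.frame(name = "Na", charge = 1, concIn = 150,
#'                         concOut = 150, permeability = 1))
#' @export
ghkCondition <- function(ions, temperatureK = 294) {
  req <- c("name", "charge", "concIn", "concOut", "permeability")
  if (!is.data.frame(ions) || nrow(ions) == 0L)
    .stopCondition("iglur_config_error",
                   "ghkCondition: at least one permeant ion is required")
  if (!all(req %in% names(ions)))
    .stopCondition("iglur_config_error", paste(
      "ghkCondition: ions must have columns", paste(req, collapse = ", ")))
  if (!all(ions$charge %in% c(1, 2)))
    .stopCondition("iglur_config_error", "ion charges must be +1 or +2")
  if (any(ions$concIn < 0) || any(ions$concOut < 0))
    .stopCondition("iglur_config_error", "concentrations must be >= 0")
  if (any(ions$permeability < 0))
    .stopCondition("iglur_config_error", "permeabilities must be >= 0")
  if (!any(ions$concIn * ions$permeability > 0) ||
      !any(ions$concOut * ions$permeability > 0))
    .stopCondition("iglur_config_error",
                   "need a permeant ion on each side of the membrane")
  stopifnot(temperatureK > 0)
  structure(list(ions = ions, temperatureK = temperatureK),
            class = "GHKCondition")
}

# GHK flux term for one ion: u = zFV/RT;
# I ~ P z^2 F u (Cin - Cout e^{-u}) / (1 - e^{-u}), with the analytic u -> 0
# limit P z F (Cin - Cout) substituted near the singularity.
.ghkIonTerm <- function(u, z, cin, cout) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-6
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- z * us * (cin - cout * exp(-us)) / (-expm1(-us))
  }
  if (any(small)) {
    us <- u[small]
    out[small] <- z * ((cin - cout) + us * (cin + cout) / 2)
  }
  out
}

#' Goldman-Hodgkin-Katz current over a set of ions
#'
#' Sums the GHK constant-field flux over all ions in `cond` at the given
#' voltages. Divalent ions use the z = 2 form. The absolute scale is set by
#' `gain` (permeabilities are relative); reversal potentials are independent
#' of it.
#'
#' @param cond a [ghkCondition()] object.
#' @param voltagesMV numeric, membrane voltages in mV.
#' @param gain multiplicative patch gain mapping flux units to pA
#'   (default 1e-5, giving currents of order hundreds of pA for typical
#'   150 mM conditions).
#' @return numeric currents (pA), one per voltage.
#' @examples
#' cond <- ghkCondition(data.frame(name = "Na", charge = 1, concIn = 150,
#'                                 concOut = 150, permeability = 1))
#' ghkCurrent(cond, 0)  # zero by symmetry
#' @export
ghkCurrent <- function(cond, voltagesMV, gain = 1e-5) {
  stopifnot(inherits(cond, "GHKCondition"))
  pc <- physicalConstants(cond$temperatureK)
  v <- voltagesMV / 1000
  total <- numeric(length(v))
  for (i in seq_len(nrow(cond$ions))) {
    ion <- cond$ions[i, ]
    u <- ion$charge * v / pc$rtOverF
    total <- total + ion$permeability * ion$charge *
      .ghkIonTerm(u, ion$charge, ion$concIn, ion$concOut)
  }
  gain * pc$F * total
}
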