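#' @import methods
NULL

#' IVSeries: peak current versus command voltage
#'
#' Container for a current-voltage (I-V) relationship recorded under one ionic
#' condition: per-voltage peak currents (pA) at strictly increasing command
#' voltages (mV), plus free-form condition metadata (ions, ligand, blocker,
#' simulation ground truth).
#'
#' @slot voltages numeric, command voltages in mV, strictly increasing.
#' @slot currents numeric, peak currents in pA (same length as `voltages`).
#' @slot condition list of free-form metadata.
#' @slot normalization `"raw"` or `"to_current_at_anchor"`.
#' @slot anchor numeric(0) when raw, otherwise the anchor voltage in mV.
#' @export
setClass("IVSeries",
  representation(
    voltages = "numeric",
    currents = "numeric",
    condition = "list",
    normalization = "character",
    anchor = "numeric"
  ),
  prototype(condition = list(), normalization = "raw", anchor = numeric(0))
)

setValidity("IVSeries", function(object) {
  msg <- character(0)
  if (length(object@voltages) != length(object@currents))
    msg <- c(msg, "voltages and currents must have equal length")
  if (length(object@voltages) < 4L)
    msg <- c(msg, "an IVSeries needs at least 4 points")
  if (any(diff(object@voltages) <= 0))
    msg <- c(msg, "voltages must be strictly increasing")
  if (!object@normalization %in% c("raw", "to_current_at_anchor"))
    msg <- c(msg, "normalization must be 'raw' or 'to_current_at_anchor'")
  if (object@normalization == "to_current_at_anchor" &&
      length(object@anchor) != 1L)
    msg <- c(msg, "normalized series must record their anchor voltage")
  if (length(msg)) msg else TRUE
})

#' Construct an IVSeries
#'
#' @param voltages numeric, mV, strictly increasing (>= 4 points).
#' @param currents numeric, pA.
#' @param condition list of metadata describing the recording condition.
#' @param normalization `"raw"` (default) or `"to_current_at_anchor"`.
#' @param anchor anchor voltage (mV) when normalized.
#' @return An [IVSeries-class] object.
#' @examples
#' iv <- IVSeries(seq(-100, 100, 10), 2 * (seq(-100, 100, 10) - 10))
#' @export
IVSeries <- function(voltages, currents, condition = list(),
                     normalization = "raw", anchor = numeric(0)) {
  new("IVSeries", voltages = as.numeric(voltages),
      currents = as.numeric(currents), condition = condition,
      normalization = normalization, anchor = as.numeric(anchor))
}

#' GVSeries: conductance versus voltage
#'
#' Conductance (nS, or dimensionless once normalized) against command voltage,
#' with an explicit record of the reversal potential used, which points were
#' excluded around the singularity at Vrev, and the normalization state.
#'
#' @slot voltages numeric, mV.
#' @slot conductance numeric; `NA` at excluded voltages.
#' @slot vrevUsed numeric(1), reversal potential (mV) used for G = I/(V - Vrev).
#' @slot excluded logical, TRUE where the conductance was not evaluated.
#' @slot normalization `"raw"`, `"to_max"`, or `"to_anchor_voltage"`.
#' @slot anchor anchor voltage when normalized to an anchor.
#' @slot referenceValue the raw conductance value used as normalization
#'   reference (retained so normalization is invertible).
#' @slot condition list of metadata.
#' @export
setClass("GVSeries",
  representation(
    voltages = "numeric",
    conductance = "numeric",
    vrevUsed = "numeric",
    excluded = "logical",
    normalization = "character",
    anchor = "numeric",
    referenceValue = "numeric",
    condition = "list"
  ),
  prototype(vrevUsed = NA_real_, normalization = "raw", anchor = numeric(0),
            referenceValue = numeric(0), condition = list())
)

setValidity("GVSeries", function(object) {
  msg <- character(0)
  n <- length(object@voltages)
  if (length(object@conductance) != n || length(object@excluded) != n)
    msg <- c(msg, "voltages, conductance and excluded must have equal length")
  if (any(diff(object@voltages) <= 0))
    msg <- c(msg, "voltages must be strictly increasing")
  if (any(!is.finite(object@conductance[!object@excluded])))
    msg <- c(msg, "conductance must be finite at all retained voltages")
  if (!object@normalization %in% c("raw", "to_max", "to_anchor_voltage"))
    msg <- c(msg, "unknown normalization mode")
  if (length(msg)) msg else TRUE
})

#' Construct a GVSeries
#'
#' @param voltages numeric, mV.
#' @param conductance numeric (nS or normalized); `NA` allowed at excluded
#'   points.
#' @param vrevUsed reversal potential (mV) the conductance was computed with.
#' @param excluded logical flags; defaults to `is.na(conductance)`.
#' @param normalization,anchor,referenceValue normalization state.
#' @param condition list of metadata.
#' @return A [GVSeries-class] object.
#' @export
GVSeries <- function(voltages, conductance, vrevUsed = NA_real_,
                     excluded = NULL, normalization = "raw",
                     anchor = numeric(0), referenceValue = numeric(0),
                     condition = list()) {
  if (is.null(excluded)) excluded <- is.na(conductance)
  new("GVSeries", voltages = as.numeric(voltages),
      conductance = as.numeric(conductance), vrevUsed = as.numeric(vrevUsed),
      excluded = as.logical(excluded), normalization = normalization,
      anchor = as.numeric(anchor), referenceValue = as.numeric(referenceValue),
      condition = condition)
}

#' ReversalEstimate: polynomial reversal-potential estimate
#'
#' @slot erev estimated reversal potential (mV).
#' @slot degree polynomial degree actually used (reduced when data are few).
#' @slot window voltage window (mV) used for the fit.
#' @slot rms residual root-mean-square of the polynomial fit (pA).
#' @slot nPoints number of points in the fit.
#' @export
setClass("ReversalEstimate",
  representation(erev = "numeric", degree = "integer", window = "numeric",
                 rms = "numeric", nPoints = "integer"))

#' BlockerFit: single permeant blocker model parameters
#'
#' Parameters of G(V) = Gmax / (1 + \[Spm\]/Kd(V)) with
#' Kd(V) = g e^(V/h) + L e^(V/k). `g` and `L` are the 0 mV ratios
#' k_off/k_on and k_perm/k_on (µM); `h` (mV, negative) and `k` (mV, positive)
#' are their voltage dependencies; `kd0 = g + L` is the dissociation constant
#' at 0 mV.
#'
#' @slot gmax maximal conductance (nS, or normalized units).
#' @slot g,L µM components of Kd at 0 mV.
#' @slot h,k voltage dependencies (mV); h < 0 (block onset), k > 0 (relief).
#' @slot kd0 µM, equals g + L.
#' @slot spm fixed spermine concentration (µM) the fit was conditioned on.
#' @slot window voltage window used.
#' @slot diagnostics list: residual `rms`, `converged`, parameter standard
#'   errors `se`, correlation `corGL` of the g/L estimates, `nPoints`.
#' @export
setClass("BlockerFit",
  representation(gmax = "numeric", g = "numeric", h = "numeric",
                 L = "numeric", k = "numeric", kd0 = "numeric",
                 spm = "numeric", window = "numeric", diagnostics = "list"))

setValidity("BlockerFit", function(object) {
  msg <- character(0)
  if (object@g < 0 || object@L < 0) msg <- c(msg, "g and L must be >= 0")
  if (!isTRUE(all.equal(object@kd0, object@g + object@L)))
    msg <- c(msg, "kd0 must equal g + L")
  if (is.finite(object@h) && object@h >= 0) msg <- c(msg, "h must be negative")
  if (is.finite(object@k) && object@k <= 0) msg <- c(msg, "k must be positive")
  if (object@spm <= 0) msg <- c(msg, "spm must be positive")
  if (length(msg)) msg else TRUE
})

#' IntrinsicFit: exponential fit of a block-free G-V relationship
#'
#' G(V) = 1 + (G0 - 1) e^(V/Vc) on the normalized conductance scale.
#'
#' @slot g0 fitted minimal conductance G0.
#' @slot vc voltage constant Vc (mV); `NA` when unidentifiable.
#' @slot empiricalMin observed minimum conductance (reported separately from
#'   the fitted G0).
#' @slot diagnostics list with `rms` and `converged`.
#' @export
setClass("IntrinsicFit",
  representation(g0 = "numeric", vc = "numeric", empiricalMin = "numeric",
                 diagnostics = "list"))

setValidity("IntrinsicFit", function(object) {
  if (is.finite(object@vc) && object@vc == 0) "vc must be nonzero" else TRUE
})

#' DoseTable: normalized dose-response observations
#'
#' @slot concentrations numeric, > 0 (zero-concentration control rows are
#'   carried separately as anchors by the fitters).
#' @slot responses numeric, normalized peak currents.
#' @slot ligand name of the ligand or drug.
#' @slot direction `"activation"` or `"inhibition"`.
#' @slot unit concentration unit tag (e.g. `"mM"`, `"uM"`).
#' @export
setClass("DoseTable",
  representation(concentrations = "numeric", responses = "numeric",
                 ligand = "character", direction = "character",
                 unit = "character"))

setValidity("DoseTable", function(object) {
  msg <- character(0)
  if (length(object@concentrations) != length(object@responses))
    msg <- c(msg, "concentrations and responses must have equal length")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (any(!is.finite(object@responses)))
    msg <- c(msg, "responses must be finite")
  if (!object@direction %in% c("activation", "inhibition"))
    msg <- c(msg, "direction must be 'activation' or 'inhibition'")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseTable
#'
#' @param concentrations numeric ligand concentrations (in `unit`).
#' @param responses normalized responses.
#' @param ligand ligand name.
#' @param direction `"activation"` (default) or `"inhibition"`.
#' @param unit concentration unit tag, default `"mM"`.
#' @return A [DoseTable-class] object.
#' @export
doseTable <- function(concentrations, responses, ligand = "ligand",
                      direction = "activation", unit = "mM") {
  new("DoseTable", concentrations = as.numeric(concentrations),
      responses = as.numeric(responses), ligand = ligand,
      direction = direction, unit = unit)
}

#' HillFit: monophasic dose-response fit
#'
#' @slot ec50 midpoint concentration (EC50 for activation, IC50 for
#'   inhibition), in the table's unit.
#' @slot hillSlope Hill slope p.
#' @slot direction `"activation"` or `"inhibition"`.
#' @slot unit concentration unit tag.
#' @slot diagnostics list with `rms`, `converged`, `se`.
#' @export
setClass("HillFit",
  representation(ec50 = "numeric", hillSlope = "numeric",
                 direction = "character", unit = "character",
                 diagnostics = "list"))

setValidity("HillFit", function(object) {
  if (is.finite(object@ec50) && object@ec50 <= 0) "ec50 must be > 0" else TRUE
})

#' BiphasicFit: one stimulatory and one inhibitory dose-response phase
#'
#' y(c) = (1 + a c^ns / (EC50s^ns + c^ns)) (1 - c^ni / (IC50i^ni + c^ni)).
#'
#' @slot stimAmplitude a >= 0 (fractional potentiation).
#' @slot ec50Stim,slopeStim stimulatory midpoint and slope.
#' @slot ic50Inhib,slopeInhib inhibitory midpoint and slope.
#' @slot unit concentration unit tag.
#' @slot diagnostics list with `rms`, `converged`, `fallback`.
#' @export
setClass("BiphasicFit",
  representation(stimAmplitude = "numeric", ec50Stim = "numeric",
                 slopeStim = "numeric", ic50Inhib = "numeric",
                 slopeInhib = "numeric", unit = "character",
                 diagnostics = "list"))

#' RecoveryFit: single-exponential recovery from desensitization
#'
#' y(x) = 1 + A e^(-x/tau), with A expected in (-1, 0].
#'
#' @slot amplitude fitted A (dimensionless, expected negative).
#' @slot tau time constant (ms).
#' @slot diagnostics list with `rms`, `converged`, `tauIdentifiable`.
#' @export
setClass("RecoveryFit",
  representation(amplitude = "numeric", tau = "numeric",
                 diagnostics = "list"))

setValidity("RecoveryFit", function(object) {
  if (is.finite(object@tau) && object@tau <= 0) "tau must be > 0" else TRUE
})

#' PermeabilityResult: relative permeability from a bi-ionic reversal potential
#'
#' @slot ratio dimensionless permeability ratio (> 0 under the Lewis form).
#' @slot kind `"monovalent_over_monovalent"` or `"divalent_over_monovalent"`.
#' @slot erevInputs the reversal potentials (mV) the ratio was computed from.
#' @slot condition list describing the bi-ionic condition.
#' @export
setClass("PermeabilityResult",
  representation(ratio = "numeric", kind = "character",
                 erevInputs = "numeric", condition = "list"))

#' ReferenceMap: query-to-reference residue numbering map
#'
#' Strictly monotone mapping from 1-based query residue coordinates to mature
#' rat GluA2 reference numbering, from a global pairwise alignment.
#'
#' @slot queryId,refId sequence identifiers.
#' @slot map data.frame with one row per reference position: `refPos`,
#'   `queryPos` (NA where the query has an alignment gap) and `queryChar`
#'   (the aligned query character, `"-"` at gaps).
#' @slot refLength length of the reference.
#' @slot score alignment score.
#' @slot coverage fraction of ligand-binding-domain reference positions
#'   aligned to query residues.
#' @export
setClass("ReferenceMap",
  representation(queryId = "character", refId = "character",
                 map = "data.frame", refLength = "integer",
                 score = "numeric", coverage = "numeric"))

setValidity("ReferenceMap", function(object) {
  m <- object@map
  msg <- character(0)
  if (!all(c("refPos", "queryPos") %in% names(m))) {
    msg <- c(msg, "map must have refPos and queryPos columns")
  } else {
    mm <- m[!is.na(m$queryPos), , drop = FALSE]
    if (nrow(mm) > 1 &&
        (any(diff(mm$refPos) <= 0) || any(diff(mm$queryPos) <= 0)))
      msg <- c(msg, "map must be strictly monotone")
  }
  if (length(msg)) msg else TRUE
})

#' SiteProfile: residues at the deterministic GluA2-numbered positions
#'
#' @slot sites named character: residues at the backbone-contact positions
#'   (450, 478, 480, 485, 654, 705) and side-chain-contact positions
#'   (653, 655, 704, 708, 732); `"-"` for an alignment gap, `"unmapped"` for
#'   positions outside the mapped region.
#' @slot qrn residue at the pore Q/R/N site (reference position 607).
#' @slot plus4 residue 4 positions downstream of the Q/R/N site in the
#'   query's own (ungapped) coordinates.
#' @slot m3Motif 9-character string at the SYTANLAAF (M3 gate) locus.
#' @slot lurcher residue at the lurcher alanine position.
#' @slot siteG 2-character string at site G.
#' @slot warnings character vector of extraction warnings.
#' @export
setClass("SiteProfile",
  representation(sites = "character", qrn = "character", plus4 = "character",
                 m3Motif = "character", lurcher = "character",
                 siteG = "character", warnings = "character"))

#' LigandPrediction: rule-based ligand specificity call
#'
#' @slot label `"glutamate"`, `"glycine/D-serine"`, or `"unpredictable"`.
#' @slot warnings advisory flags (e.g. `missing_D705`, `missing_R485`,
#'   `gap_at_site`); warnings never change the label.
#' @export
setClass("LigandPrediction",
  representation(label = "character", warnings = "character"))

setValidity("LigandPrediction", function(object) {
  ok <- object@label %in% c("glutamate", "glycine/D-serine", "unpredictable")
  if (!ok) "unknown prediction label" else TRUE
})
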