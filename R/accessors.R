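# Accessor generics and show methods.

#' @describeIn IVSeries-class command voltages (mV)
#' @param object an object
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))

#' @describeIn IVSeries-class peak currents (pA)
#' @export
setGeneric("currents", function(object) standardGeneric("currents"))

#' @describeIn GVSeries-class conductance values (NA at excluded voltages)
#' @export
setGeneric("conductance", function(object) standardGeneric("conductance"))

#' @describeIn ReversalEstimate-class estimated reversal potential (mV)
#' @export
setGeneric("erev", function(object) standardGeneric("erev"))

#' @describeIn BlockerFit-class dissociation constant at 0 mV (µM)
#' @export
setGeneric("kd0", function(object) standardGeneric("kd0"))

#' @describeIn BlockerFit-class named parameter vector (gmax, g, h, L, k, kd0, spm)
#' @export
setGeneric("blockerParams", function(object) standardGeneric("blockerParams"))

#' @rdname IVSeries-class
#' @export
setMethod("voltages", "IVSeries", function(object) object@voltages)

#' @rdname GVSeries-class
#' @export
setMethod("voltages", "GVSeries", function(object) object@voltages)

#' @rdname IVSeries-class
#' @export
setMethod("currents", "IVSeries", function(object) object@currents)

#' @rdname GVSeries-class
#' @export
setMethod("conductance", "GVSeries", function(object) object@conductance)

#' @rdname ReversalEstimate-class
#' @export
setMethod("erev", "ReversalEstimate", function(object) object@erev)

#' @rdname BlockerFit-class
#' @export
setMethod("kd0", "BlockerFit", function(object) object@kd0)

#' @rdname BlockerFit-class
#' @export
setMethod("blockerParams", "BlockerFit", function(object) {
  c(gmax = object@gmax, g = object@g, h = object@h, L = object@L,
    k = object@k, kd0 = object@kd0, spm = object@spm)
})

setMethod("show", "IVSeries", function(object) {
  cat(sprintf("IVSeries: %d points, %g to %g mV (%s)\n",
              length(object@voltages), min(object@voltages),
              max(object@voltages), object@normalization))
  if (length(object@condition))
    cat("  condition:", paste(names(object@condition), collapse = ", "), "\n")
})

setMethod("show", "GVSeries", function(object) {
  cat(sprintf(
    "GVSeries: %d points (%d excluded), Vrev = %.3g mV, normalization = %s\n",
    length(object@voltages), sum(object@excluded), object@vrevUsed,
    object@normalization))
})

setMethod("show", "ReversalEstimate", function(object) {
  cat(sprintf(
    "ReversalEstimate: Erev = %.4g mV (degree %d, %d points, rms %.3g)\n",
    object@erev, object@degree, object@nPoints, object@rms))
})

setMethod("show", "BlockerFit", function(object) {
  cat("Single permeant blocker fit:\n")
  cat(sprintf("  Kd(0 mV) = %.4g uM  (g = %.4g, L = %.4g)\n",
              object@kd0, object@g, object@L))
  cat(sprintf("  h = %.4g mV, k = %.4g mV, Gmax = %.4g, [Spm] = %g uM\n",
              object@h, object@k, object@gmax, object@spm))
  cat(sprintf("  converged: %s, residual rms: %.3g\n",
              object@diagnostics$converged, object@diagnostics$rms))
})

setMethod("show", "IntrinsicFit", function(object) {
  cat(sprintf(
    "Intrinsic G-V fit: G0 = %.4g, Vc = %.4g mV (empirical min %.4g)\n",
    object@g0, object@vc, object@empiricalMin))
})

setMethod("show", "HillFit", function(object) {
  lbl <- if (object@direction == "activation") "EC50" else "IC50"
  cat(sprintf("Hill fit (%s): %s = %.4g %s, slope = %.3g\n",
              object@direction, lbl, object@ec50, object@unit,
              object@hillSlope))
})

setMethod("show", "BiphasicFit", function(object) {
  cat(sprintf(
    "Biphasic fit: EC50(stim) = %.4g %s (a = %.3g), IC50(inhib) = %.4g %s\n",
    object@ec50Stim, object@unit, object@stimAmplitude, object@ic50Inhib,
    object@unit))
})

setMethod("show", "RecoveryFit", function(object) {
  cat(sprintf("Recovery fit: tau = %.4g ms, A = %.3g\n",
              object@tau, object@amplitude))
})

setMethod("show", "PermeabilityResult", function(object) {
  cat(sprintf("Permeability ratio (%s): %.4g\n", object@kind, object@ratio))
})

setMethod("show", "SiteProfile", function(object) {
  cat("SiteProfile (mature GluA2 numbering):\n")
  cat("  sites:", paste(names(object@sites), object@sites, sep = "=",
                        collapse = " "), "\n")
  cat(sprintf("  Q/R/N = %s, +4 = %s, M3 = %s\n",
              object@qrn, object@plus4, object@m3Motif))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = ", "), "\n")
})

setMethod("show", "LigandPrediction", function(object) {
  cat("Predicted ligand specificity:", object@label, "\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = ", "), "\n")
})
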