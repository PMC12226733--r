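# I-V to G-V conversion, normalization, and the 0 mV conductance-difference
# statistic.

#' Convert an I-V series to conductance
#'
#' G = I / (V - Vrev), in nS when I is in pA and V in mV. Voltages within
#' `exclusionHalfwidth` of the reversal potential are flagged as excluded
#' (conductance `NA`), not silently dropped, to guard against the singularity
#' at Vrev.
#'
#' @param iv an [IVSeries-class].
#' @param erev reversal potential (mV); an [ReversalEstimate-class] is also
#'   accepted.
#' @param exclusionHalfwidth half-width (mV) of the exclusion band around
#'   Vrev, default 2.5.
#' @return A [GVSeries-class] with `normalization = "raw"`.
#' @examples
#' v <- seq(-100, 100, 10)
#' gv <- computeConductance(IVSeries(v, 5 * v), erev = 0)
#' @export
computeConductance <- function(iv, erev, exclusionHalfwidth = 2.5) {
  stopifnot(is(iv, "IVSeries"))
  if (is(erev, "ReversalEstimate")) erev <- erev@erev
  stopifnot(is.finite(erev), exclusionHalfwidth >= 0)
  v <- iv@voltages
  excl <- abs(v - erev) <= exclusionHalfwidth
  if (all(excl))
    .stopCondition("iglur_config_error",
                   "all voltages fall inside the exclusion band around Vrev")
  g <- ifelse(excl, NA_real_, iv@currents / (v - erev))
  GVSeries(v, g, vrevUsed = erev, excluded = excl,
           condition = iv@condition)
}

#' Normalize a G-V series
#'
#' `to_max` divides by the maximal retained conductance; `to_anchor_voltage`
#' divides by the (interpolated) conductance at the anchor voltage. The raw
#' reference value is retained in the result so the operation is auditable.
#'
#' @param gv a [GVSeries-class].
#' @param mode `"to_max"` or `"to_anchor_voltage"`.
#' @param anchor anchor voltage (mV), required for `"to_anchor_voltage"`.
#' @return A normalized [GVSeries-class].
#' @export
normalizeGV <- function(gv, mode = c("to_max", "to_anchor_voltage"),
                        anchor = -100) {
  stopifnot(is(gv, "GVSeries"))
  mode <- match.arg(mode)
  keep <- !gv@excluded & is.finite(gv@conductance)
  ref <- switch(mode,
    to_max = max(gv@conductance[keep]),
    to_anchor_voltage = .interpAt(gv@voltages[keep], gv@conductance[keep],
                                  anchor))
  if (!is.finite(ref) || ref == 0)
    .stopCondition("iglur_config_error",
                   "normalization reference value is zero or undefined")
  GVSeries(gv@voltages, gv@conductance / ref, vrevUsed = gv@vrevUsed,
           excluded = gv@excluded, normalization = mode,
           anchor = if (mode == "to_anchor_voltage") anchor else numeric(0),
           referenceValue = ref, condition = gv@condition)
}

#' Normalized conductance difference at 0 mV
#'
#' 100 (G_variant(0) - G_reference(0)) on the shared normalized scale, the
#' statistic used to compare polyamine block across receptor variants. Both
#' series must be normalized with the same mode; the conductance at 0 mV is
#' linearly interpolated from neighbours when 0 mV itself is excluded or
#' absent.
#'
#' @param gvVariant,gvReference normalized [GVSeries-class] objects.
#' @return percent difference (percentage points on the normalized scale);
#'   negative values mean more block in the variant.
#' @export
conductanceDiffAtZero <- function(gvVariant, gvReference) {
  stopifnot(is(gvVariant, "GVSeries"), is(gvReference, "GVSeries"))
  if (gvVariant@normalization == "raw" || gvReference@normalization == "raw" ||
      gvVariant@normalization != gvReference@normalization)
    .stopCondition("iglur_config_error",
                   "both series must be normalized with the same mode")
  gAt0 <- function(gv) {
    keep <- !gv@excluded & is.finite(gv@conductance)
    .interpAt(gv@voltages[keep], gv@conductance[keep], 0)
  }
  100 * (gAt0(gvVariant) - gAt0(gvReference))
}
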