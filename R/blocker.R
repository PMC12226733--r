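# The single permeant blocker model: closed forms and nonlinear fitting.

#' Voltage-dependent dissociation constant of the permeant blocker
#'
#' Kd(V) = g e^(V/h) + L e^(V/k). With h < 0 the first (block onset) branch
#' grows with hyperpolarization and with k > 0 the second (permeation/relief)
#' branch grows with depolarization, so Kd has a unique interior minimum when
#' both g and L are positive.
#'
#' @param g,L µM components of Kd at 0 mV (g = k_off/k_on, L = k_perm/k_on).
#' @param h,k voltage dependencies (mV) of g and L.
#' @param v voltage(s), mV.
#' @return Kd in µM, vectorized over `v`.
#' @examples
#' kdOfV(10, -18.5, 1.4, 36.5, 0)  # g + L = 11.4
#' @export
kdOfV <- function(g, h, L, k, v) {
  g * exp(v / h) + L * exp(v / k)
}

.blockerPars <- function(object) {
  if (is(object, "BlockerFit")) {
    list(gmax = object@gmax, g = object@g, h = object@h, L = object@L,
         k = object@k, spm = object@spm)
  } else if (is.list(object)) {
    stopifnot(all(c("gmax", "g", "h", "L", "k") %in% names(object)))
    object
  } else {
    stop("expected a BlockerFit or a named parameter list")
  }
}

#' Predicted conductance under the single permeant blocker model
#'
#' G(V) = Gmax / (1 + \[Spm\] / Kd(V)).
#'
#' @param object a [BlockerFit-class] or a named list with `gmax`, `g`, `h`,
#'   `L`, `k` (and optionally `spm`).
#' @param v voltage(s), mV.
#' @param spm spermine concentration (µM); defaults to the one stored in
#'   `object`.
#' @return conductance, same units as `gmax`.
#' @examples
#' truth <- blockerTruth()
#' predictG(truth, seq(-100, 100, 10))
#' @export
predictG <- function(object, v, spm = NULL) {
  p <- .blockerPars(object)
  if (is.null(spm)) spm <- p$spm
  stopifnot(!is.null(spm), spm >= 0)
  p$gmax / (1 + spm / kdOfV(p$g, p$h, p$L, p$k, v))
}

.retainedGV <- function(gv, window) {
  keep <- !gv@excluded & is.finite(gv@conductance)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- keep & gv@voltages >= min(window) & gv@voltages <= max(window)
  }
  list(v = gv@voltages[keep], g = gv@conductance[keep])
}

#' Fit the single permeant blocker model to a G-V relationship
#'
#' Bounded Levenberg-Marquardt least squares of
#' G(V) = Gmax / (1 + \[Spm\]/(g e^(V/h) + L e^(V/k))), with g and L fitted in
#' log space (positivity), h constrained negative and k positive. The spermine
#' concentration is a fixed experimental input, never a free parameter:
#' doubling \[Spm\] together with g and L leaves the model invariant, so a
#' free \[Spm\] would be unidentifiable.
#'
#' Initialization follows the conductance at 0 mV: Kd(0) = \[Spm\] G/(Gmax - G)
#' with Gmax started at the maximal observed conductance, split 85:15 between
#' the g and L branches, h at -20 mV and k at +30 mV.
#'
#' Block-free inputs are refused rather than fit: a zero spermine
#' concentration, or a conductance profile with no resolvable voltage-dependent
#' modulation, raises an error of class `iglur_block_free`.
#'
#' @param gv a [GVSeries-class].
#' @param spm spermine concentration, µM (> 0).
#' @param window optional `c(vmin, vmax)` voltage window (mV); points outside
#'   are excluded from the objective.
#' @param init optional named list overriding the default start values
#'   (`gmax`, `g`, `L`, `h`, `k`).
#' @param gmaxFixed fix Gmax at 1 instead of fitting it (sensible on
#'   max-normalized data). When fitted on max-normalized data Gmax is bounded
#'   to \[0.8, 1.2\].
#' @return A [BlockerFit-class].
#' @examples
#' sim <- simulateGVBlocker(blockerTruth())
#' fitBlocker(sim$gv, spm = 30)
#' @export
fitBlocker <- function(gv, spm, window = NULL, init = NULL,
                       gmaxFixed = FALSE) {
  stopifnot(is(gv, "GVSeries"))
  if (spm < 0) .stopCondition("iglur_config_error", "spm must be >= 0")
  if (spm == 0)
    .stopCondition("iglur_block_free",
                   "blocker fit refused: [Spm] = 0, the data are block-free")
  d <- .retainedGV(gv, window)
  if (length(d$v) < 6L)
    .stopCondition("iglur_config_error",
                   "blocker fit needs at least 6 points inside the window")
  gRange <- diff(range(d$g))
  if (gRange <= 1e-6 * max(abs(d$g)))
    .stopCondition("iglur_block_free", paste(
      "blocker fit refused: conductance shows no voltage-dependent",
      "modulation (block-free data)"))

  gmax0 <- max(d$g)
  g0v <- tryCatch(.interpAt(d$v, d$g, 0), error = function(e) NA_real_)
  kd0i <- if (is.finite(g0v) && g0v > 0 && g0v < gmax0) {
    spm * g0v / (gmax0 - g0v)
  } else {
    spm
  }
  start <- list(gmax = gmax0, g = 0.85 * kd0i, L = 0.15 * kd0i,
                h = -20, k = 30)
  if (!is.null(init)) start[names(init)] <- init

  normalizedScale <- gv@normalization == "to_max"
  lowerGmax <- if (normalizedScale && !gmaxFixed) 0.8 else 1e-9
  upperGmax <- if (normalizedScale && !gmaxFixed) 1.2 else 1e9

  # spm rides along in the data so the optimizer can never treat it as free
  df <- data.frame(v = d$v, G = d$g, spmFixed = spm)
  mkForm <- function(fixed) {
    if (fixed) {
      G ~ 1 / (1 + spmFixed / (exp(lg) * exp(v / h) + exp(lL) * exp(v / k)))
    } else {
      G ~ gmax /
        (1 + spmFixed / (exp(lg) * exp(v / h) + exp(lL) * exp(v / k)))
    }
  }
  startPar <- list(lg = log(max(start$g, 1e-6)),
                   lL = log(max(start$L, 1e-6)),
                   h = start$h, k = start$k)
  lower <- c(lg = log(1e-8), lL = log(1e-8), h = -500, k = 0.5)
  upper <- c(lg = log(1e8), lL = log(1e8), h = -0.5, k = 1000)
  if (!gmaxFixed) {
    startPar <- c(list(gmax = min(max(start$gmax, lowerGmax), upperGmax)),
                  startPar)
    lower <- c(gmax = lowerGmax, lower)
    upper <- c(gmax = upperGmax, upper)
  }

  # The objective is multimodal in (h, k); a single LM start can park in a
  # shallow local minimum. Run a small deterministic multi-start over typical
  # voltage-dependence scales and keep the lowest-RSS solution.
  hGrid <- c(-10, -20, -40)
  kGrid <- c(15, 30, 60, 150)
  starts <- c(list(startPar),
              unlist(lapply(hGrid, function(h0) lapply(kGrid, function(k0) {
                s <- startPar; s$h <- h0; s$k <- k0; s
              })), recursive = FALSE))
  runOne <- function(s) tryCatch(
    minpack.lm::nlsLM(mkForm(gmaxFixed), data = df, start = s,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  fit <- NULL
  for (s in starts) {
    cand <- runOne(s)
    if (is.null(cand)) next
    if (is.null(fit) ||
        sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)) fit <- cand
  }
  if (is.null(fit))
    .stopCondition("iglur_fit_error", "blocker fit did not converge")

  cf <- stats::coef(fit)
  gmaxHat <- if (gmaxFixed) 1 else unname(cf["gmax"])
  gHat <- exp(unname(cf["lg"]))
  LHat <- exp(unname(cf["lL"]))
  hHat <- unname(cf["h"])
  kHat <- unname(cf["k"])
  res <- stats::resid(fit)
  conv <- isTRUE(fit$convInfo$isConv)

  se <- tryCatch({
    sm <- summary(fit)$coefficients
    out <- sm[, "Std. Error"]
    # delta-method back-transform for the log-space parameters
    out["lg"] <- out["lg"] * gHat
    out["lL"] <- out["lL"] * LHat
    names(out)[names(out) == "lg"] <- "g"
    names(out)[names(out) == "lL"] <- "L"
    out
  }, error = function(e) NULL)
  corGL <- tryCatch({
    vc <- stats::vcov(fit)
    vc["lg", "lL"] / sqrt(vc["lg", "lg"] * vc["lL", "lL"])
  }, error = function(e) NA_real_)

  new("BlockerFit", gmax = gmaxHat, g = gHat, h = hHat, L = LHat, k = kHat,
      kd0 = gHat + LHat, spm = spm,
      window = if (is.null(window)) range(d$v) else as.numeric(window),
      diagnostics = list(rms = sqrt(mean(res^2)), converged = conv,
                         se = se, corGL = corGL, nPoints = length(d$v),
                         gmaxFixed = gmaxFixed))
}

#' Fit the intrinsic (block-free) exponential G-V relationship
#'
#' G(V) = 1 + (G0 - 1) e^(V/Vc) on the normalized conductance scale, for
#' channels without voltage-dependent block (e.g. after neutralizing the +4
#' aspartate). The fitted G0 and the empirical minimum conductance are
#' reported separately.
#'
#' @param gv a [GVSeries-class] (>= 4 retained points).
#' @return An [IntrinsicFit-class]. For constant input the amplitude is
#'   degenerate: G0 is the mean level, Vc is `NA` and the fit is flagged
#'   non-converged.
#' @export
fitIntrinsic <- function(gv) {
  stopifnot(is(gv, "GVSeries"))
  d <- .retainedGV(gv, NULL)
  if (length(d$v) < 4L)
    .stopCondition("iglur_config_error",
                   "intrinsic fit needs at least 4 points")
  if (diff(range(d$g)) <= 1e-9 * max(1, max(abs(d$g)))) {
    return(new("IntrinsicFit", g0 = mean(d$g), vc = NA_real_,
               empiricalMin = min(d$g),
               diagnostics = list(rms = 0, converged = FALSE,
                                  note = "constant conductance: Vc unidentifiable")))
  }
  # coarse grid over Vc with conditionally linear G0, then LM polish
  vcGrid <- c(-200, -120, -63, -30, -15, 15, 30, 63, 120, 200)
  best <- NULL
  for (vc in vcGrid) {
    b <- exp(d$v / vc)
    sl <- tryCatch(unname(stats::lm.fit(cbind(b), d$g - 1)$coefficients[1]),
                   error = function(e) NA_real_)
    if (!is.finite(sl)) next
    rss <- sum((1 + sl * b - d$g)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(vc = vc, g0 = 1 + sl, rss = rss)
  }
  df <- data.frame(v = d$v, G = d$g)
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ 1 + (g0 - 1) * exp(v / vc), data = df,
                      start = list(g0 = best$g0, vc = best$vc),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    .stopCondition("iglur_fit_error",
                   paste("intrinsic fit did not converge:",
                         conditionMessage(fit)))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  new("IntrinsicFit", g0 = unname(cf["g0"]), vc = unname(cf["vc"]),
      empiricalMin = min(d$g),
      diagnostics = list(rms = sqrt(mean(res^2)),
                         converged = isTRUE(fit$convInfo$isConv)))
}
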