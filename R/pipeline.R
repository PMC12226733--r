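# Pipeline driver and report assembly.

#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration: ambient temperature
#' 294 K, internal spermine 30 µM, a -100..+100 mV voltage grid in 10 mV
#' steps, and generator truths matching the wildtype study conditions
#' (blocker Kd(0 mV) = 11.4 µM split 10:1.4 with h = -18.5 mV and
#' k = 36.5 mV; dose-response EC50 = 0.11 mM; recovery tau = 184 ms).
#'
#' @param outDir output directory for the report bundle.
#' @param seed integer seed applied to every synthetic input.
#' @return named list, the resolved `RunConfig`.
#' @export
defaultRunConfig <- function(outDir = tempfile("iglurphys_run_"), seed = 1) {
  list(
    seed = seed,
    outDir = outDir,
    temperatureK = 294,
    spmUM = 30,
    voltages = seq(-100, 100, 10),
    noiseSD = 0.02,
    exclusionHalfwidth = 2.5,
    normalizationMode = "to_max",
    blockerTruth = list(gmax = 1, g = 10, h = -18.5, L = 1.4, k = 36.5,
                        vrev = 0),
    dose = list(ec50 = 0.11, hillSlope = 1.5, unit = "mM",
                ligand = "glycine"),
    recovery = list(tau = 184, amplitude = -0.9),
    stages = c("simulate", "iv", "blocker", "dose", "recovery", "sites"),
    verbosity = 1
  )
}

.validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    .stopCondition("iglur_config_error",
                   "config must be a list or a YAML file path")
  base <- defaultRunConfig()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  numOk <- function(x) is.numeric(x) && all(is.finite(x))
  if (!numOk(base$seed) || !numOk(base$temperatureK) || !numOk(base$spmUM) ||
      !numOk(base$voltages) || !numOk(base$noiseSD))
    .stopCondition("iglur_config_error",
                   "config fields seed/temperatureK/spmUM/voltages/noiseSD must be numeric")
  if (base$spmUM < 0)
    .stopCondition("iglur_config_error", "spmUM must be >= 0")
  if (base$temperatureK <= 0)
    .stopCondition("iglur_config_error", "temperatureK must be > 0")
  base$voltages <- sort(unique(base$voltages))
  base
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes the requested stages in dependency order (simulate, I-V
#' analysis, blocker fitting, dose-response and recovery kinetics, site
#' annotation), writes TSV tables and a JSON report carrying the fully
#' resolved configuration, every seed, and the package version, and leaves a
#' MANIFEST of the files written. Stage errors abort with the failing stage
#' named; a block-free refusal from the blocker fitter (e.g. `spmUM = 0`)
#' is recorded as a diagnostic instead of an estimate.
#'
#' @param config a configuration list (see [defaultRunConfig()]) or the path
#'   to a YAML file; missing fields take their defaults.
#' @return invisibly, the report list (also written to
#'   `<outDir>/report.json`).
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- .validateConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  report <- list(config = cfg,
                 package = list(name = "iGluRphys",
                                version = as.character(
                                  utils::packageVersion("iGluRphys"))))
  say <- function(...) if (cfg$verbosity > 0) message(sprintf(...))
  runStage <- function(name, expr) {
    tryCatch(expr, iglur_block_free = function(e) e, error = function(e)
      .stopCondition("iglur_stage_error",
                     sprintf("stage '%s' failed: %s", name,
                             conditionMessage(e))))
  }

  # -- simulate + iv/gv + blocker ------------------------------------------
  if (any(c("simulate", "iv", "blocker") %in% cfg$stages)) {
    say("simulate: GHK bi-ionic I-V (seed %d)", cfg$seed)
    cond <- ghkCondition(data.frame(
      name = c("Na_in", "Na_out"), charge = 1,
      concIn = c(150, 0), concOut = c(0, 150), permeability = 1),
      temperatureK = cfg$temperatureK)
    iv <- runStage("simulate", simulateIV(cond, cfg$voltages,
                                          noiseSD = cfg$noiseSD,
                                          seed = cfg$seed))
    files <- c(files, .writeTSV(
      data.frame(voltage_mV = voltages(iv), current_pA = currents(iv)),
      file.path(cfg$outDir, "iv_ghk.tsv")))

    simB <- runStage("simulate",
                     simulateGVBlocker(blockerTruth(
                       gmax = cfg$blockerTruth$gmax, g = cfg$blockerTruth$g,
                       h = cfg$blockerTruth$h, L = cfg$blockerTruth$L,
                       k = cfg$blockerTruth$k, spm = cfg$spmUM,
                       vrev = cfg$blockerTruth$vrev),
                       cfg$voltages, noiseSD = cfg$noiseSD,
                       seed = cfg$seed + 1L))
    files <- c(files, .writeTSV(
      data.frame(voltage_mV = voltages(simB$gv),
                 conductance = conductance(simB$gv)),
      file.path(cfg$outDir, "gv_blocker.tsv")))

    if ("iv" %in% cfg$stages) {
      est <- runStage("iv", estimateReversal(iv))
      gv <- runStage("iv", computeConductance(
        iv, est, exclusionHalfwidth = cfg$exclusionHalfwidth))
      report$iv <- list(erev_mV = erev(est), degree = est@degree,
                        rms_pA = est@rms, nPoints = est@nPoints)
      files <- c(files, .writeTSV(
        data.frame(voltage_mV = voltages(gv), conductance_nS = conductance(gv),
                   excluded = gv@excluded),
        file.path(cfg$outDir, "gv_from_iv.tsv")))
    }

    if ("blocker" %in% cfg$stages) {
      say("blocker: single permeant blocker fit ([Spm] = %g uM)", cfg$spmUM)
      fit <- runStage("blocker", fitBlocker(simB$gv, spm = cfg$spmUM))
      if (inherits(fit, "iglur_block_free")) {
        report$blocker <- list(refusal = conditionMessage(fit),
                               spm_uM = cfg$spmUM)
      } else {
        report$blocker <- list(
          kd0_uM = fit@kd0, g_uM = fit@g, L_uM = fit@L,
          h_mV = fit@h, k_mV = fit@k, gmax = fit@gmax,
          spm_uM = fit@spm, converged = fit@diagnostics$converged,
          rms = fit@diagnostics$rms,
          truth = cfg$blockerTruth)
      }
    }
  }

  # -- dose-response -------------------------------------------------------
  if ("dose" %in% cfg$stages) {
    say("dose: Hill fit (truth EC50 = %g %s)", cfg$dose$ec50, cfg$dose$unit)
    tab <- runStage("dose", simulateDoseResponse(
      cfg$dose$ec50, cfg$dose$hillSlope, noiseSD = cfg$noiseSD,
      seed = cfg$seed + 2L, unit = cfg$dose$unit, ligand = cfg$dose$ligand))
    hf <- runStage("dose", fitHill(tab))
    report$dose <- list(ec50 = hf@ec50, hillSlope = hf@hillSlope,
                        unit = hf@unit, converged = hf@diagnostics$converged,
                        truth = cfg$dose)
    files <- c(files, .writeTSV(
      data.frame(conc = tab@concentrations, response = tab@responses,
                 unit = tab@unit),
      file.path(cfg$outDir, "dose_response.tsv")))
  }

  # -- recovery ------------------------------------------------------------
  if ("recovery" %in% cfg$stages) {
    say("recovery: exponential fit (truth tau = %g ms)", cfg$recovery$tau)
    rec <- runStage("recovery", simulateRecovery(
      cfg$recovery$tau, amplitude = cfg$recovery$amplitude,
      noiseSD = cfg$noiseSD, seed = cfg$seed + 3L))
    rf <- runStage("recovery", fitRecovery(rec$interval_ms, rec$ratio))
    report$recovery <- list(tau_ms = rf@tau, amplitude = rf@amplitude,
                            converged = rf@diagnostics$converged,
                            truth = cfg$recovery)
    files <- c(files, .writeTSV(rec,
                                file.path(cfg$outDir, "recovery.tsv")))
  }

  # -- site annotation -----------------------------------------------------
  if ("sites" %in% cfg$stages) {
    say("sites: residue annotation of a glycine-receptor-like fixture")
    fx <- runStage("sites", simulateAlignmentFixture(
      c("653" = "S", "655" = "I", "732" = "F"),
      mutationRate = 0.02, seed = cfg$seed + 4L,
      queryId = "glycine_like_query"))
    ann <- runStage("sites", annotateSites(fx[2]))
    report$sites <- as.list(ann[1, ])
    files <- c(files, .writeTSV(ann, file.path(cfg$outDir, "sites.tsv")))
  }

  reportPath <- file.path(cfg$outDir, "report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, reportPath)
  writeLines(basename(files), file.path(cfg$outDir, "MANIFEST"))
  invisible(report)
}

#' Assemble an equilibrium-block summary table
#'
#' One row per receptor: Kd(0 mV) in µM with its h and k voltage
#' dependencies for permeant-blocker fits, and `"-"` in those cells for
#' receptors whose linear (block-free) G-V was fit with the intrinsic
#' exponential instead.
#'
#' @param fits named list of [BlockerFit-class] and/or [IntrinsicFit-class]
#'   objects (>= 1).
#' @param n optional integer vector of recording counts per receptor.
#' @return data.frame with columns `receptor`, `Kd0mV_uM`, `h_mV`, `k_mV`,
#'   `n`.
#' @export
makeTable1Report <- function(fits, n = NULL) {
  if (!is.list(fits) || length(fits) == 0L)
    .stopCondition("iglur_config_error", "need at least one fit")
  nms <- if (is.null(names(fits))) paste0("receptor", seq_along(fits)) else
    names(fits)
  if (is.null(n)) n <- rep(NA_integer_, length(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (is(f, "BlockerFit")) {
      data.frame(receptor = nms[i],
                 Kd0mV_uM = sprintf("%.3g", f@kd0),
                 h_mV = sprintf("%.3g", f@h),
                 k_mV = sprintf("%.3g", f@k),
                 n = n[i], stringsAsFactors = FALSE)
    } else if (is(f, "IntrinsicFit")) {
      data.frame(receptor = nms[i], Kd0mV_uM = "-", h_mV = "-", k_mV = "-",
                 n = n[i], stringsAsFactors = FALSE)
    } else {
      .stopCondition("iglur_config_error",
                     "fits must be BlockerFit or IntrinsicFit objects")
    }
  })
  do.call(rbind, rows)
}
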