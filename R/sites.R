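# Mapping sequences onto mature GluA2 numbering, site extraction, and the
# residue-rule ligand-specificity classifier.

.asAAString <- function(x) {
  if (is(x, "AAString")) return(x)
  if (is(x, "AAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1]])
  }
  Biostrings::AAString(x)
}

#' Map a query protein onto the reference numbering
#'
#' Global pairwise alignment (BLOSUM62, affine gaps) of the query against the
#' mature-GluA2-numbered reference, yielding a strictly monotone map from
#' query residue coordinates to reference positions. Mapping reliability is
#' judged by coverage over the two ligand-binding-domain segments; below the
#' threshold an `iglur_unreliable_mapping` error is raised.
#'
#' @param query protein sequence (character, `AAString`, or single-sequence
#'   `AAStringSet`), >= 50 residues, standard amino-acid alphabet (X
#'   tolerated).
#' @param reference reference sequence; defaults to the bundled
#'   [glua2Reference()]. If a full-length precursor is supplied, give the
#'   signal-peptide length as `signalOffset` so positions are reported in
#'   mature numbering.
#' @param signalOffset residues to subtract from reference coordinates
#'   (default 0 for the bundled mature-numbered reference).
#' @param gapOpening,gapExtension affine gap penalties.
#' @param coverageThreshold minimum fraction of ligand-binding-domain
#'   reference positions aligned to query residues (default 0.3).
#' @param queryId identifier stored in the map.
#' @return A [ReferenceMap-class].
#' @examples
#' m <- mapToReference(glua2Reference())
#' m@coverage  # 1 for self-mapping
#' @export
mapToReference <- function(query, reference = glua2Reference(),
                           signalOffset = 0, gapOpening = 10,
                           gapExtension = 0.5, coverageThreshold = 0.3,
                           queryId = "query") {
  if (is(query, "AAStringSet") && length(query) == 1L &&
      !is.null(names(query))) queryId <- names(query)[1]
  q <- .asAAString(query)
  r <- .asAAString(reference)
  if (length(q) < 50L || length(r) < 50L)
    .stopCondition("iglur_config_error",
                   "query and reference must each have >= 50 residues")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", as.character(q)))
    .stopCondition("iglur_config_error",
                   "query contains non-standard amino-acid characters")

  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    q, r, type = "global", substitutionMatrix = get("BLOSUM62"),
    gapOpening = gapOpening, gapExtension = gapExtension)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  nRef <- length(r)
  refPosAll <- as.integer(seq_len(nRef) - signalOffset)
  queryPos <- rep(NA_integer_, nRef)
  queryChar <- rep("-", nRef)
  qi <- 0L; ri <- 0L
  for (idx in seq_along(ra)) {
    rGap <- ra[idx] == "-"
    qGap <- qa[idx] == "-"
    if (!qGap) qi <- qi + 1L
    if (!rGap) {
      ri <- ri + 1L
      if (!qGap) {
        queryPos[ri] <- qi
        queryChar[ri] <- qa[idx]
      }
    }
  }
  map <- data.frame(refPos = refPosAll, queryPos = queryPos,
                    queryChar = queryChar, stringsAsFactors = FALSE)

  segs <- referenceSites()$lbdSegments
  segPos <- unlist(lapply(segs, function(s) seq(s[1], s[2])))
  segPos <- segPos[segPos >= min(refPosAll) & segPos <= max(refPosAll)]
  covered <- !is.na(map$queryPos[match(segPos, map$refPos)])
  coverage <- mean(covered)
  if (coverage < coverageThreshold)
    .stopCondition("iglur_unreliable_mapping", sprintf(
      "unreliable mapping: LBD coverage %.2f below threshold %.2f",
      coverage, coverageThreshold))

  new("ReferenceMap", queryId = queryId, refId = "GluA2_mature",
      map = map, refLength = nRef, score = Biostrings::score(aln),
      coverage = coverage)
}

.charAtRef <- function(map, pos) {
  i <- match(pos, map@map$refPos)
  if (is.na(i)) "unmapped" else map@map$queryChar[i]
}

#' Extract residues at the deterministic GluA2-numbered sites
#'
#' Reads the query residues at the ligand backbone-contact positions (450,
#' 478, 480, 485, 654, 705), the side-chain-contact positions (653, 655,
#' 704, 708, 732), the pore Q/R/N site (607) and its +4 site, plus the
#' SYTANLAAF (M3), lurcher and site-G annotations. The +4 residue is read 4
#' residues downstream of the Q/R/N residue in the query's own ungapped
#' coordinates. Alignment gaps are reported as `"-"`; positions outside the
#' mapped region as `"unmapped"`, each with a warning flag in the profile.
#'
#' @param map a [ReferenceMap-class] from [mapToReference()].
#' @param query the query sequence the map was built from.
#' @return A [SiteProfile-class].
#' @export
extractSites <- function(map, query) {
  stopifnot(is(map, "ReferenceMap"))
  qChars <- strsplit(as.character(.asAAString(query)), "")[[1]]
  sites <- referenceSites()
  warningsOut <- character(0)

  allPos <- c(sites$backbone, sites$sidechain)
  res <- vapply(allPos, function(p) .charAtRef(map, p), character(1))
  names(res) <- as.character(allPos)
  bad <- res %in% c("-", "unmapped")
  if (any(bad))
    warningsOut <- c(warningsOut,
                     paste0("gap_at_site_", names(res)[bad]))

  qrnChar <- .charAtRef(map, sites$qrn)
  qrnIdx <- map@map$queryPos[match(sites$qrn, map@map$refPos)]
  if (qrnChar %in% c("-", "unmapped")) {
    warningsOut <- c(warningsOut, "gap_at_qrn")
    plus4 <- "unmapped"
  } else if (is.na(qrnIdx) || qrnIdx + sites$plus4Offset > length(qChars)) {
    plus4 <- "unmapped"
    warningsOut <- c(warningsOut, "plus4_outside_query")
  } else {
    plus4 <- qChars[qrnIdx + sites$plus4Offset]
  }

  m3 <- paste(vapply(seq(sites$m3[1], sites$m3[2]),
                     function(p) .charAtRef(map, p), character(1)),
              collapse = "")
  lurcher <- .charAtRef(map, sites$lurcher)
  siteG <- paste(vapply(sites$siteG, function(p) .charAtRef(map, p),
                        character(1)), collapse = "")

  new("SiteProfile", sites = res, qrn = qrnChar, plus4 = plus4,
      m3Motif = m3, lurcher = lurcher, siteG = siteG,
      warnings = warningsOut)
}

#' Rule-based prediction of glutamate vs. glycine/D-serine specificity
#'
#' Applies the residue rules at the three deterministic side-chain-contact
#' positions: glutamate specificity requires G/S/T at 653, T at 655 and Y at
#' 732; glycine/D-serine specificity requires S at 653, a hydrophobic residue
#' (V/L/A/I/P) at 655 and F at 732. Profiles matching neither rule (the two
#' rule sets are mutually exclusive by construction at positions 655/732)
#' are `"unpredictable"`. Advisory warnings are emitted when the backbone
#' anchors are missing (no D at 705, no R at 485) or when a rule site is a
#' gap; warnings never change the label.
#'
#' @param profile a [SiteProfile-class].
#' @return A [LigandPrediction-class].
#' @examples
#' predictLigandFromResidues("S", "I", "F")  # glycine/D-serine
#' @export
predictLigand <- function(profile) {
  stopifnot(is(profile, "SiteProfile"))
  s <- profile@sites
  pred <- predictLigandFromResidues(s[["653"]], s[["655"]], s[["732"]])
  warningsOut <- pred@warnings
  if (!identical(s[["705"]], "D"))
    warningsOut <- c(warningsOut, "missing_D705")
  if (!identical(s[["485"]], "R"))
    warningsOut <- c(warningsOut, "missing_R485")
  new("LigandPrediction", label = pred@label, warnings = warningsOut)
}

#' @describeIn predictLigand apply the rules directly to the three residues
#'   at positions 653, 655 and 732.
#' @param r653,r655,r732 single residue letters (or `"-"`/`"unmapped"`).
#' @export
predictLigandFromResidues <- function(r653, r655, r732) {
  warningsOut <- character(0)
  resLike <- function(x) nchar(x) == 1L && grepl("^[A-Z]$", x)
  if (!resLike(r653) || !resLike(r655) || !resLike(r732)) {
    warningsOut <- "gap_at_site"
    return(new("LigandPrediction", label = "unpredictable",
               warnings = warningsOut))
  }
  glu <- r653 %in% c("G", "S", "T") && r655 == "T" && r732 == "Y"
  gly <- r653 == "S" && r655 %in% c("V", "L", "A", "I", "P") && r732 == "F"
  label <- if (glu) "glutamate" else if (gly) "glycine/D-serine" else
    "unpredictable"
  new("LigandPrediction", label = label, warnings = warningsOut)
}

#' Annotate a set of sequences against the reference
#'
#' Convenience wrapper: maps every sequence, extracts its site profile and
#' predicts ligand specificity, returning one row per query.
#'
#' @param seqs a `Biostrings::AAStringSet` (or named character vector).
#' @param ... passed to [mapToReference()].
#' @return data.frame with the site residues, Q/R/N, +4, motif annotations,
#'   the predicted label and collapsed warnings.
#' @export
annotateSites <- function(seqs, ...) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  ids <- if (is.null(names(seqs))) paste0("query", seq_along(seqs)) else
    names(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    m <- mapToReference(seqs[[i]], queryId = ids[i], ...)
    prof <- extractSites(m, seqs[[i]])
    pred <- predictLigand(prof)
    out <- c(list(id = ids[i]), as.list(prof@sites),
             list(qrn = prof@qrn, plus4 = prof@plus4,
                  m3_motif = prof@m3Motif, lurcher = prof@lurcher,
                  site_G = prof@siteG, prediction = pred@label,
                  warnings = paste(unique(c(prof@warnings, pred@warnings)),
                                   collapse = ";"),
                  coverage = m@coverage))
    as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  })
  do.call(rbind, rows)
}
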