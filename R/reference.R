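# Bundled reference scaffold and its annotated site coordinates.

#' The bundled GluA2-numbered reference sequence
#'
#' Returns the synthetic mature-GluA2-numbered reference scaffold shipped
#' with the package. It is not the natural rat GluA2 sequence: it is a
#' deterministic synthetic scaffold that carries the documented residue
#' identities at every annotated position (Q at the Q/R/N site 607, D at the
#' +4 site 611, the ligand-binding-domain contact residues, the SYTANLAAF M3
#' motif, the lurcher alanine and the site-G alanine-threonine pair), so that
#' sequences aligned against it inherit mature GluA2 numbering at those
#' positions. Users with the natural P19491 sequence can pass it to
#' [mapToReference()] directly instead.
#'
#' @return A `Biostrings::AAString`.
#' @examples
#' substr(as.character(glua2Reference()), 607, 611)  # "QEEYD"
#' @export
glua2Reference <- function() {
  path <- system.file("extdata", "glua2_synthetic_reference.fasta",
                      package = "iGluRphys", mustWork = TRUE)
  set <- Biostrings::readAAStringSet(path)
  set[[1]]
}

#' Annotated site coordinates on the reference numbering
#'
#' Coordinates (mature GluA2 numbering for the ligand-binding-domain and
#' pore anchor positions; scaffold-defined coordinates, recorded here, for
#' the M3/site-G motifs) of every deterministic position the annotation
#' extracts.
#'
#' @return list with elements `backbone` (ligand backbone-contact positions
#'   450, 478, 480, 485, 654, 705), `sidechain` (side-chain-contact positions
#'   653, 655, 704, 708, 732), `qrn` (607), `plus4Offset` (4), `m3`
#'   (start/end of the SYTANLAAF locus), `lurcher`, `siteG`, and
#'   `lbdSegments` (the S1 and S2 segments used for mapping coverage).
#' @export
referenceSites <- function() {
  list(
    backbone = c(450L, 478L, 480L, 485L, 654L, 705L),
    sidechain = c(653L, 655L, 704L, 708L, 732L),
    qrn = 607L,
    plus4Offset = 4L,
    m3 = c(616L, 624L),
    lurcher = 623L,
    siteG = c(598L, 599L),
    lbdSegments = list(s1 = c(430L, 543L), s2 = c(692L, 816L))
  )
}
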