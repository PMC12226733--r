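# Reference mapping, site extraction and the ligand-specificity rules.

test_that("self-mapping is the identity with full coverage", {
  ref <- glua2Reference()
  m <- mapToReference(ref)
  expect_equal(m@coverage, 1)
  mm <- m@map[!is.na(m@map$queryPos), ]
  expect_identical(mm$refPos, mm$queryPos)
})

test_that("a leading deletion shifts all mapped positions consistently", {
  ref <- as.character(glua2Reference())
  query <- substr(ref, 11, nchar(ref))
  m <- mapToReference(query)
  mm <- m@map[!is.na(m@map$queryPos), ]
  expect_true(all(mm$refPos - mm$queryPos == 10))
})

test_that("site extraction round-trips planted residues across random fixtures", {
  sites <- referenceSites()
  plantable <- c(sites$backbone, sites$sidechain)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(404)
  for (rep in 1:60) {
    pos <- sample(plantable, 3)
    res <- sample(aa, 3, replace = TRUE)
    spec <- stats::setNames(res, pos)
    fx <- simulateAlignmentFixture(spec, mutationRate = 0.02,
                                  seed = sample.int(1e6, 1))
    prof <- extractSites(mapToReference(fx[[2]]), fx[[2]])
    expect_identical(unname(prof@sites[as.character(pos)]), unname(res))
  }
})

test_that("the bundled reference self-annotates with canonical pore residues", {
  ref <- glua2Reference()
  prof <- extractSites(mapToReference(ref), ref)
  expect_identical(prof@qrn, "Q")
  expect_identical(prof@plus4, "D")
  expect_identical(prof@m3Motif, "SYTANLAAF")
  expect_identical(prof@lurcher, "A")
  expect_identical(prof@siteG, "AT")
  expect_identical(predictLigand(prof)@label, "glutamate")
})

test_that("ligand rules reproduce the canonical triads", {
  expect_identical(predictLigandFromResidues("S", "I", "F")@label,
                   "glycine/D-serine")
  expect_identical(predictLigandFromResidues("G", "T", "Y")@label,
                   "glutamate")
  # conflicting halves of the two rules are unpredictable
  expect_identical(predictLigandFromResidues("S", "T", "F")@label,
                   "unpredictable")
  expect_identical(predictLigandFromResidues("-", "T", "Y")@label,
                   "unpredictable")
})

test_that("backbone-anchor warnings are advisory and never change the label", {
  fx <- simulateAlignmentFixture(c("653" = "S", "655" = "I", "732" = "F",
                                  "705" = "A", "485" = "K"))
  prof <- extractSites(mapToReference(fx[[2]]), fx[[2]])
  pred <- predictLigand(prof)
  expect_identical(pred@label, "glycine/D-serine")
  expect_true(all(c("missing_D705", "missing_R485") %in% pred@warnings))
})

test_that("unrelated sequences are refused as unreliable mappings", {
  set.seed(99)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                       replace = TRUE), collapse = "")
  expect_error(mapToReference(junk), class = "iglur_unreliable_mapping")
  expect_error(mapToReference("MKV"), class = "iglur_config_error")
  expect_error(mapToReference(paste(rep("B", 100), collapse = "")),
               class = "iglur_config_error")
})
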