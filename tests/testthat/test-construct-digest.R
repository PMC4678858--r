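test_that("scaffold-guided assembly reproduces the junction sequences", {
  oli <- assayOligos("Et")
  insert <- ODN(ligate(oli$linker10mer,
                       setFivePrime(oli$lesion12mer, "phosphate")),
                fivePrime = "phosphate")
  gc <- assembleConstruct(insert, oli$scaffold1, oli$scaffold2)

  # oracle: the flanks are the scaffold reverse complements minus the
  # insert-overlapping parts
  rc1 <- oracleRevComp(as.character(oli$scaffold1))
  rc2 <- oracleRevComp(as.character(oli$scaffold2))
  expect_equal(as.character(gc@upstreamFlank),
               substr(rc1, 1, nchar(rc1) - 8))   # ...GATTCAGTG
  expect_equal(as.character(gc@downstreamFlank),
               substr(rc2, 6, nchar(rc2)))        # AATTCACTGG...
  expect_match(attr(gc, "junctions")[["upstream"]],
               "GATTCAGTG\\|AGTGGAAG")
  expect_match(attr(gc, "junctions")[["downstream"]],
               "GCTAT\\|AATTCACT")
  expect_equal(lesionPositions(gc@insert), 16L)

  # a mismatched base in the annealing region breaks the bridge
  badScaffold <- ODN("AAAACGACGGCCAGTGAATTAGAGC")  # one base changed
  expect_error(assembleConstruct(insert, oli$scaffold1, badScaffold),
               "fails to bridge")
  expect_error(assembleConstruct(ODN(as.character(insert)),
                                 oli$scaffold1, oli$scaffold2),
               "5'-phosphorylated")
})

test_that("the control construct has identical coordinates and no lesion", {
  les <- defaultConstruct("lesion", alkyl = "Et")
  ctl <- defaultConstruct("control")
  expect_equal(nchar(topStrand(ctl)), nchar(topStrand(les)))
  expect_equal(topStrand(ctl), gsub("X", "T", topStrand(les)))
  expect_equal(nrow(lesionTable(ctl@insert)), 0L)
})

test_that("amplicon extraction is primer-bounded and single-site", {
  oli <- assayOligos()
  ctl <- defaultConstruct("control")
  amp <- extractAmplicon(ctl, oli$fwdPrimer, oli$revPrimer)
  top <- as.character(amp@top)
  expect_true(startsWith(top, as.character(oli$fwdPrimer)))
  expect_true(endsWith(top, oracleRevComp(as.character(oli$revPrimer))))
  expect_equal(as.character(amp@bottom), oracleRevComp(top))
  expect_equal(fivePrime(amp@top), "amino_blocked")

  expect_error(extractAmplicon(ctl, ODN("TTTTTTTTTTTTTTTT"), oli$revPrimer),
               "exactly once")
  # without the synthetic downstream vector context the reverse primer
  # has no site
  bare <- defaultConstruct("control", vectorContext = list())
  expect_error(extractAmplicon(bare, oli$fwdPrimer, oli$revPrimer),
               "exactly once")
})

test_that("restriction site finding matches REBASE cut geometry", {
  e <- defaultEnzymes()
  amp <- controlAmplicon()
  top <- as.character(amp@top)

  bbsi <- findSites(amp, e$BbsI)
  expect_equal(nrow(bbsi), 1L)
  # top cut 2 nt after the recognition (between ...GAAGACAT | GGCG...),
  # bottom cut 6 nt after: a 4-nt 5' overhang
  site <- regexpr("GAAGAC", top, fixed = TRUE)[1] - 1L
  expect_equal(bbsi$topCut, site + 8L)
  expect_equal(bbsi$bottomCut, site + 12L)
  expect_equal(substr(top, bbsi$topCut - 1, bbsi$topCut), "AT")
  expect_equal(substr(top, bbsi$topCut + 1, bbsi$topCut + 4), "GGCG")

  mluci <- findSites(amp, e$MluCI)
  expect_equal(nrow(mluci), 1L)
  expect_equal(substr(top, mluci$topCut + 1, mluci$topCut + 4), "AATT")
  expect_equal(mluci$bottomCut - mluci$topCut, 4L)  # AATT 5' overhang

  ecori <- findSites("TTGAATTCAA", e$EcoRI)  # G^AATTC
  expect_equal(ecori$topCut, 3L)
  expect_equal(ecori$bottomCut, 7L)

  # both orientations are found; oracle agreement on a two-site substrate
  two <- "AAGAAGACAAAAAAAAAAAAAAGTCTTCAA"
  got <- findSites(two, e$BbsI)
  want <- oracleSites(two, "GAAGAC", 8, 12)
  expect_setequal(got$topCut, want$top)
  expect_setequal(got$bottomCut, want$bottom)
})

test_that("digestion order selects which strand's 10-mer is labeled", {
  schemes <- canonicalSchemes()
  amp <- controlAmplicon()

  f1 <- sequentialDigestLabel(amp, schemes[["BbsI-first"]],
                              visibleOnly = TRUE)
  short1 <- f1[f1$length <= 13, ]
  expect_equal(nrow(short1), 1L)
  expect_equal(short1$sequence, "GGCGTGCTAT")
  expect_equal(short1$strand, "top")
  expect_equal(short1$length, 10L)

  f2 <- sequentialDigestLabel(amp, schemes[["MluCI-first"]],
                              visibleOnly = TRUE)
  short2 <- f2[f2$length <= 13, ]
  expect_equal(short2$sequence, "AATTATAGCA")
  expect_equal(short2$strand, "bottom")

  # label count equals the number of first-digestion-created 5' termini;
  # switching the order swaps the labeled strand's short product, never both
  expect_false(any(f1$strand == "bottom" & f1$length <= 13))
  expect_false(any(f2$strand == "top" & f2$length <= 13))

  # oracle agreement on the full labeled fragment set
  top <- as.character(amp@top)
  for (sch in list(c("BbsI", "MluCI"), c("MluCI", "BbsI"))) {
    got <- sequentialDigestLabel(amp, assayScheme(sch[1], sch[2]))
    want <- oracleDigest(top, sch[1], sch[2])
    key <- function(d) sort(paste(d$strand, d$start, d$end, d$labeled))
    expect_equal(key(got), key(want))
  }

  expect_error(assayScheme("BbsI", "MluCI", dephosphorylate = FALSE),
               "missing a required step")
  expect_error(assayScheme("BbsI", "MluCI", label = FALSE),
               "missing a required step")
  expect_error(assayScheme("FokI", "MluCI"), "not found")
})

test_that("loss of a recognition site is scored as lack of bypass", {
  amp <- controlAmplicon()
  top <- as.character(amp@top)
  # large-deletion mimic: excise the region containing the BbsI site
  noBbsI <- duplexRegion(gsub("GAAGAC", "", top, fixed = TRUE))
  f <- sequentialDigestLabel(noBbsI, assayScheme("BbsI", "MluCI"))
  expect_false(isBypassDetectable(f))
  expect_true(isBypassDetectable(
    sequentialDigestLabel(amp, assayScheme("BbsI", "MluCI"))))
})

test_that("enumeration yields the four substitution outcomes plus optional frameshifts", {
  les <- defaultConstruct("lesion", alkyl = "Me")
  out <- enumerateOutcomes(les)
  expect_named(out, c("M_T", "M_C", "M_A", "M_G"))
  expect_equal(length(out), 4L)

  sch <- canonicalSchemes()
  released <- vapply(out, function(d) {
    f <- sequentialDigestLabel(d, sch[["BbsI-first"]], visibleOnly = TRUE)
    f$sequence[f$length == 10]
  }, character(1))
  expect_equal(unname(released),
               c("GGCGTGCTAT", "GGCGCGCTAT", "GGCGAGCTAT", "GGCGGGCTAT"))
  # bottom strand carries the complement of M
  releasedN <- vapply(out, function(d) {
    f <- sequentialDigestLabel(d, sch[["MluCI-first"]], visibleOnly = TRUE)
    f$sequence[f$length == 10]
  }, character(1))
  expect_equal(unname(releasedN),
               c("AATTATAGCA", "AATTATAGCG", "AATTATAGCT", "AATTATAGCC"))

  withDel <- enumerateOutcomes(les, includeDeletions = TRUE)
  expect_equal(length(withDel), 6L)
  f9 <- sequentialDigestLabel(withDel$del1, sch[["BbsI-first"]],
                              visibleOnly = TRUE)
  expect_true("GGCGGCTAT" %in% f9$sequence[f9$length == 9])
  f8 <- sequentialDigestLabel(withDel$del2, sch[["BbsI-first"]],
                              visibleOnly = TRUE)
  expect_true("GGCGCTAT" %in% f8$sequence[f8$length == 8])

  # control construct: the M = T outcome is the input amplicon itself
  ctl <- defaultConstruct("control")
  outCtl <- enumerateOutcomes(ctl, site = 16L)
  expect_equal(as.character(outCtl$M_T@top),
               as.character(controlAmplicon()@top))
  expect_error(enumerateOutcomes(ctl), "exactly one")
})

test_that("digestion conserves the sequence on random substrates", {
  set.seed(7)
  schemes <- canonicalSchemes()
  for (i in 1:40) {
    s <- randomSeq(sample(40:120, 1))
    # half the substrates get guaranteed sites spliced in
    if (i %% 2 == 0)
      s <- paste0(substr(s, 1, 20), "GAAGACNN", substr(s, 21, 30),
                  "AATT", substr(s, 31, nchar(s)))
    s <- gsub("N", "A", s)
    d <- duplexRegion(s)
    for (sch in schemes) {
      f <- sequentialDigestLabel(d, sch)
      topF <- f[f$strand == "top", ]
      topF <- topF[order(topF$start), ]
      expect_equal(paste(topF$sequence, collapse = ""), s)
      botF <- f[f$strand == "bottom", ]
      botF <- botF[order(-botF$start), ]
      expect_equal(paste(botF$sequence, collapse = ""), oracleRevComp(s))
      # labeled termini are exactly the first enzyme's cuts
      e1 <- sch$enzymes[[sch$first]]
      sites1 <- findSites(d, e1)
      expect_equal(sum(f$labeled),
                   sum(topF$start %in% sites1$topCut) +
                   sum(botF$end %in% sites1$bottomCut))
    }
  }
})
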