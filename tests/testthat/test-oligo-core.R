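test_that("reverse complement follows the complement table and is an involution", {
  expect_equal(as.character(reverseComplement(ODN("GGCGTGCTAT"))),
               "ATAGCACGCC")
  expect_equal(as.character(reverseComplement(ODN("AATT"))), "AATT")

  # X complements as its parent base T; the paired position is recorded
  les <- ODN("ATGGCGXGCTAT", alkyl = "Et")
  rc <- reverseComplement(les)
  expect_equal(as.character(rc), "ATAGCACGCCAT")
  expect_equal(rc@opposite$position, 12L - 1L - 6L)
  back <- reverseComplement(rc)
  expect_equal(as.character(back), as.character(les))
  expect_equal(lesionTable(back), lesionTable(les))

  set.seed(42)
  for (i in 1:25) {
    s <- randomSeq(sample(5:40, 1))
    o <- ODN(s)
    expect_equal(as.character(reverseComplement(o)), oracleRevComp(s))
    expect_equal(as.character(reverseComplement(reverseComplement(o))), s)
  }

  expect_error(ODN("ATQG"), "invalid base")
})

test_that("end chemistry swaps 5'/3' roles under reverse complement", {
  o <- ODN("ACGT", fivePrime = "phosphate", threePrime = "OH")
  rc <- reverseComplement(o)
  expect_equal(fivePrime(rc), "OH")
  expect_equal(threePrime(rc), "phosphate")
})

test_that("ligation concatenates, re-indexes lesions and demands a 5'-phosphate", {
  oli <- assayOligos("Me")
  lig <- ligate(oli$linker10mer, setFivePrime(ODN("ATGGCGTGCTAT"), "phosphate"))
  expect_equal(as.character(lig), "AGTGGAAGACATGGCGTGCTAT")
  expect_equal(length(lig), 22L)

  lesLig <- ligate(oli$linker10mer, setFivePrime(oli$lesion12mer, "phosphate"))
  expect_equal(lesionPositions(lesLig), 16L)  # 10 + 6

  expect_error(ligate(oli$linker10mer, ODN("ATGGCGTGCTAT")), "not ligatable")
  expect_error(ligate(ODN("ACGT", threePrime = "phosphate"),
                      ODN("ACGT", fivePrime = "phosphate")), "3'-OH")
  expect_error(ODN(""), "non-empty")
})

test_that("monoisotopic mass matches the atomic-composition oracle", {
  cases <- list(
    list(seq = "GGCGTGCTAT", fp = "phosphate", tp = "OH", carbons = integer(0)),
    list(seq = "GGCGTGCTAT", fp = "OH", tp = "OH", carbons = integer(0)),
    list(seq = "AATTATAGCA", fp = "OH", tp = "phosphate", carbons = integer(0)),
    list(seq = "ATGGCGXGCTAT", fp = "phosphate", tp = "OH", carbons = 2L),
    list(seq = "A", fp = "OH", tp = "OH", carbons = integer(0)))
  for (cs in cases) {
    odn <- ODN(cs$seq, fivePrime = cs$fp, threePrime = cs$tp, alkyl = "Et")
    expect_equal(monoisotopicMass(odn),
                 oracleMass(cs$seq, cs$fp, cs$tp, cs$carbons),
                 tolerance = 1e-9)
  }
})

test_that("terminal and adduct mass identities hold", {
  ohM <- monoisotopicMass(ODN("GGCGTGCTAT"))
  pM <- monoisotopicMass(ODN("GGCGTGCTAT", fivePrime = "phosphate"))
  expect_equal(pM - ohM, 79.96633, tolerance = 1e-4)  # HPO3

  # CH2 increments along the homologous series
  m <- function(a) monoisotopicMass(ODN("ATGGCGXGCTAT", alkyl = a))
  expect_equal(m("Et") - m("Me"), 14.01565, tolerance = 1e-5)
  expect_equal(m("nPr") - m("Et"), 14.01565, tolerance = 1e-5)
  expect_equal(m("nBu") - m("nPr"), 14.01565, tolerance = 1e-5)
  # isomers are isobaric
  expect_equal(m("iPr"), m("nPr"))
  expect_equal(m("iBu"), m("nBu"))
  expect_equal(m("sBu_S"), m("nBu"))
  expect_equal(m("sBu_R"), m("nBu"))
})

test_that("mass is additive under ligation (condensation convention)", {
  a <- ODN("AGTGGAAGAC")
  b <- ODN("ATGGCGXGCTAT", fivePrime = "phosphate", alkyl = "nPr")
  lig <- ligate(a, b)
  expect_equal(monoisotopicMass(lig),
               monoisotopicMass(a) + monoisotopicMass(b) - 18.01056468,
               tolerance = 1e-9)
})

test_that("precursor m/z follows the deprotonation formula", {
  odn <- ODN("GGCGTGCTAT")
  M <- monoisotopicMass(odn)
  expect_equal(precursorMz(odn, 1L), M - 1.00728, tolerance = 1e-4)
  expect_equal(precursorMz(odn, 3L), oracleMz("GGCGTGCTAT", 3),
               tolerance = 1e-9)
  expect_error(precursorMz(odn, 0L), "positive integer")
  expect_error(precursorMz(odn, -2L), "positive integer")
})

test_that("fragment ladder localizes a single-base change to ions spanning it", {
  ladT <- ionTable(fragmentLadder(ODN("GGCGTGCTAT"), charges = 1L))
  ladC <- ionTable(fragmentLadder(ODN("GGCGCGCTAT"), charges = 1L))
  w_T <- ladT[ladT$series == "w", ]
  w_C <- ladC[ladC$series == "w", ]
  # position 5 (1-based) differs; w_i contains the last i residues, so
  # only indices >= 6 span it
  same <- abs(w_T$mz - w_C$mz) < 1e-9
  expect_true(all(same[w_T$index <= 5]))
  expect_true(all(!same[w_T$index >= 6]))
  # linearity: affected w ions shift by exactly the residue difference
  dRes <- oracleMass("T") - oracleMass("C")
  shift <- w_T$mz[w_T$index >= 6] - w_C$mz[w_C$index >= 6]
  expect_equal(shift, rep(dRes, sum(w_T$index >= 6)), tolerance = 1e-9)
})

test_that("complementary w/d fragments reconcile with the precursor mass", {
  odn <- ODN("GGCGTGCTAT")
  lad <- ionTable(fragmentLadder(odn, charges = 1L, series = c("w", "d")))
  M <- monoisotopicMass(odn)
  n <- length(odn)
  for (k in 1:(n - 1)) {
    wk <- lad$neutralMass[lad$series == "w" & lad$index == k][1]
    dk <- lad$neutralMass[lad$series == "d" & lad$index == n - k][1]
    # splitting one phosphodiester yields both pieces plus water uptake
    expect_equal(wk + dk, M + 79.96633052 + 18.01056468, tolerance = 1e-9)
  }
  expect_error(fragmentLadder(ODN("A")), "length >= 2")
})

test_that("the lesion registry enumerates the eight-adduct panel", {
  reg <- alkylAdducts()
  expect_equal(nrow(reg), 8L)
  expect_setequal(reg$alkyl,
                  c("Me", "Et", "nPr", "iPr", "nBu", "iBu", "sBu_S", "sBu_R"))
  expect_true(all(reg$massShift > 0))
  expect_error(ODN("X", alkyl = "cyclohexyl"), "unknown alkyl")
})
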