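# Independent oracles used by the tests.  These deliberately take a
# different route than the package: masses are computed by counting the
# atoms of the whole molecule and summing element masses; digestion is
# reproduced by naive per-position substring scanning.

# --- atomic-composition mass oracle -----------------------------------------

.elements <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, P = 30.97376151)

.nucleoside <- list(  # 2'-deoxynucleosides
  A = c(C = 10, H = 13, N = 5, O = 3),
  C = c(C = 9,  H = 13, N = 3, O = 4),
  G = c(C = 10, H = 13, N = 5, O = 4),
  T = c(C = 10, H = 14, N = 2, O = 5))

.addFormula <- function(a, b, k = 1) {
  for (el in names(b)) a[el] <- (if (is.na(a[el])) 0 else a[el]) + k * b[el]
  a
}

# whole-molecule formula: n nucleosides joined by (n-1) phosphodiester
# bridges (+HPO3 -H2O each), plus one HPO3 per terminal phosphate, plus
# CnH2n per alkyl adduct
oracleMass <- function(seq, fivePrime = "OH", threePrime = "OH",
                       alkylCarbons = integer(0)) {
  chars <- strsplit(gsub("X", "T", seq), "")[[1]]
  f <- c(C = 0, H = 0, N = 0, O = 0, P = 0)
  for (ch in chars) f <- .addFormula(f, .nucleoside[[ch]])
  nBridges <- length(chars) - 1 +
    (fivePrime %in% c("phosphate", "labeled_phosphate")) +
    (threePrime == "phosphate")
  f <- .addFormula(f, c(H = 1, P = 1, O = 3), nBridges)
  f <- .addFormula(f, c(H = 2, O = 1), -(length(chars) - 1))
  for (k in alkylCarbons) f <- .addFormula(f, c(C = k, H = 2 * k))
  sum(.elements[names(f)] * f)
}

oracleMz <- function(seq, charge, ...) {
  (oracleMass(seq, ...) - charge * 1.00727646688) / charge
}

# --- string-level sequence helpers ------------------------------------------

oracleRevComp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", X = "A")
  paste(rev(unname(map[strsplit(seq, "")[[1]]])), collapse = "")
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# --- naive digestion oracle --------------------------------------------------

# all recognition occurrences by per-position substring comparison, both
# orientations, with mirrored cut offsets for the minus orientation
oracleSites <- function(top, recognition, topCut, bottomCut) {
  len <- nchar(recognition)
  rc <- oracleRevComp(recognition)
  hits <- NULL
  for (s in seq_len(nchar(top) - len + 1)) {
    word <- substr(top, s, s + len - 1)
    if (word == recognition)
      hits <- rbind(hits, c(top = s - 1 + topCut, bottom = s - 1 + bottomCut))
    if (rc != recognition && word == rc)
      hits <- rbind(hits, c(top = s - 1 + len - bottomCut,
                            bottom = s - 1 + len - topCut))
  }
  if (is.null(hits)) return(data.frame(top = integer(0), bottom = integer(0)))
  hits <- as.data.frame(hits)
  hits <- hits[hits$top >= 0 & hits$top <= nchar(top) &
               hits$bottom >= 0 & hits$bottom <= nchar(top), , drop = FALSE]
  unique(hits)
}

.oracleEnzymes <- list(
  BbsI  = list(recognition = "GAAGAC", topCut = 8, bottomCut = 12),
  MluCI = list(recognition = "AATT",   topCut = 0, bottomCut = 4),
  EcoRI = list(recognition = "GAATTC", topCut = 1, bottomCut = 5))

# labeled fragments under a first/second digestion order: label sits on
# 5' termini created by the first enzyme (top: fragment start; bottom:
# fragment end in top coordinates)
oracleDigest <- function(top, first, second) {
  e1 <- .oracleEnzymes[[first]]; e2 <- .oracleEnzymes[[second]]
  s1 <- oracleSites(top, e1$recognition, e1$topCut, e1$bottomCut)
  s2 <- oracleSites(top, e2$recognition, e2$topCut, e2$bottomCut)
  n <- nchar(top)
  res <- NULL
  tb <- sort(unique(c(0, s1$top, s2$top, n)))
  for (i in seq_len(length(tb) - 1)) {
    a <- tb[i]; b <- tb[i + 1]
    res <- rbind(res, data.frame(
      strand = "top", start = a, end = b,
      sequence = substr(top, a + 1, b),
      labeled = a %in% s1$top, stringsAsFactors = FALSE))
  }
  bb <- sort(unique(c(0, s1$bottom, s2$bottom, n)))
  for (i in seq_len(length(bb) - 1)) {
    a <- bb[i]; b <- bb[i + 1]
    res <- rbind(res, data.frame(
      strand = "bottom", start = a, end = b,
      sequence = oracleRevComp(substr(top, a + 1, b)),
      labeled = b %in% s1$bottom, stringsAsFactors = FALSE))
  }
  res
}

# --- convenience fixtures -----------------------------------------------------

controlAmplicon <- function() {
  oli <- assayOligos()
  extractAmplicon(defaultConstruct("control"), oli$fwdPrimer, oli$revPrimer)
}

workedRunBands <- function(lesion10 = 40, comp = 20, control10 = 80,
                           compCtl = 20) {
  data.frame(
    lane = c("lesion", "lesion", "control", "control"),
    scheme = "BbsI-first",
    band = c("10mer-T/C", "13mer", "10mer-T/C", "13mer"),
    species = c("GGCGTGCTAT", "GGCGATAAGCTAT",
                "GGCGTGCTAT", "GGCGATAAGCTAT"),
    channel = c("lesion", "competitor", "control", "competitor"),
    intensity = c(lesion10, comp, control10, compCtl),
    stringsAsFactors = FALSE)
}
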