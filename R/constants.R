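# Monoisotopic mass bookkeeping.
#
# Residue masses are the standard 2'-deoxynucleoside-monophosphate chain
# residues (nucleotide minus water).  The neutral-molecule baseline is a
# 5'-OH / 3'-OH oligomer: mass = sum(residues) + H2O - HPO3; each terminal
# phosphate adds one HPO3.  All values in Da, monoisotopic.

.MASS <- list(
  residue = c(A = 313.05760514, C = 289.04637175,
              G = 329.05251976, T = 304.04603739),
  base    = c(A = 135.05449518, C = 111.04326179,
              G = 151.04940980, T = 126.04292744),
  H2O     = 18.01056468,
  HPO3    = 79.96633052,
  CH2     = 14.01565006,
  proton  = 1.00727646688
)

#' Registry of O4-alkylthymidine adducts
#'
#' The eight O4-alkyl groups examined by the assay: methyl, ethyl,
#' n-propyl, iso-propyl, n-butyl, iso-butyl and the two sec-butyl
#' diastereomers.  The monoisotopic mass shift of each adduct relative to
#' unmodified thymidine equals the mass of the added CnH2n unit
#' (alkylation of the O4 carbonyl oxygen adds CnH2n+1 and the ring loses
#' the N3 proton on tautomerisation).  Stereochemistry of the two
#' sec-butyl isomers is registry metadata only; their masses are
#' identical.
#'
#' @return A data.frame with columns `alkyl` (registry code), `carbons`
#'   (chain length) and `massShift` (Da, monoisotopic).
#' @examples
#' alkylAdducts()
#' @export
alkylAdducts <- function() {
  data.frame(
    alkyl   = c("Me", "Et", "nPr", "iPr", "nBu", "iBu", "sBu_S", "sBu_R"),
    carbons = c(1L, 2L, 3L, 3L, 4L, 4L, 4L, 4L),
    massShift = .MASS$CH2 * c(1, 2, 3, 3, 4, 4, 4, 4),
    stringsAsFactors = FALSE
  )
}

.alkylShift <- function(alkyl) {
  reg <- alkylAdducts()
  i <- match(alkyl, reg$alkyl)
  if (anyNA(i))
    stop("unknown alkyl group(s): ",
         paste(unique(alkyl[is.na(i)]), collapse = ", "))
  reg$massShift[i]
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                 # the lesion X is an O4-alkylthymidine: it retains T's
                 # Watson-Crick face and templates A in the complement
                 X = "A")

.complementBase <- function(b) {
  out <- .COMPLEMENT[b]
  if (anyNA(out))
    stop("unknown base code(s): ", paste(unique(b[is.na(out)]), collapse = ", "))
  unname(out)
}
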