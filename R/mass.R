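#' Monoisotopic mass of an ODN
#'
#' Sums standard DNA residue monoisotopic masses, adjusts for terminal
#' groups and adds the alkyl-adduct shift for every lesion.  The neutral
#' baseline convention is a 5'-OH / 3'-OH molecule; each terminal
#' phosphate adds the mass of HPO3 (79.96633 Da).  A labeled 5'-phosphate
#' is treated as an ordinary 31P phosphate: mass spectrometry in this
#' workflow only ever sees dephosphorylated (unlabeled) material, so the
#' 32P mass excess is not modeled.
#'
#' @param odn An [ODN-class].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass(ODN("GGCGTGCTAT", fivePrime = "phosphate"))
#' @export
monoisotopicMass <- function(odn) {
  stopifnot(is(odn, "ODN"))
  chars <- strsplit(odn@bases, "", fixed = TRUE)[[1]]
  res <- .MASS$residue[ifelse(chars == "X", "T", chars)]
  m <- sum(res) + .MASS$H2O - .MASS$HPO3
  if (odn@fivePrime %in% c("phosphate", "labeled_phosphate"))
    m <- m + .MASS$HPO3
  if (odn@threePrime == "phosphate")
    m <- m + .MASS$HPO3
  if (nrow(odn@lesions))
    m <- m + sum(.alkylShift(odn@lesions$alkyl))
  unname(m)
}

#' m/z of a deprotonated precursor ion
#'
#' Negative-mode ESI precursor: `[M - zH]^z-`, computed as
#' `(M - z * m_proton) / z`.
#'
#' @param odn An [ODN-class].
#' @param charge Deprotonation count `z` (positive integer).
#' @return The m/z value.
#' @examples
#' precursorMz(ODN("GGCGTGCTAT"), charge = 3)
#' @export
precursorMz <- function(odn, charge) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 ||
      charge != as.integer(charge))
    stop("charge must be a positive integer (deprotonation count)")
  (monoisotopicMass(odn) - charge * .MASS$proton) / charge
}

#' FragmentIonLadder: predicted CID product ions of an ODN
#'
#' Container for the fragment-ion series predicted for collision-induced
#' dissociation of a deprotonated oligonucleotide.
#'
#' @slot precursorMz m/z of the precursor at `charge`.
#' @slot charge Precursor deprotonation count.
#' @slot ions data.frame with columns `series` (`"w"`, `"a-B"`, `"y"` or
#'   `"d"`), `index` (1..n-1), `mz`, `charge` and `neutralMass`.
#' @exportClass FragmentIonLadder
setClass("FragmentIonLadder",
  representation(precursorMz = "numeric", charge = "integer",
                 ions = "data.frame"))

setValidity("FragmentIonLadder", function(object) {
  if (object@precursorMz <= 0) return("precursorMz must be positive")
  if (nrow(object@ions) && any(object@ions$mz <= 0))
    return("all ion m/z must be positive")
  TRUE
})

setMethod("show", "FragmentIonLadder", function(object) {
  cat(sprintf("FragmentIonLadder: precursor m/z %.4f (%d-), %d ions (%s)\n",
              object@precursorMz, object@charge, nrow(object@ions),
              paste(unique(object@ions$series), collapse = ", ")))
  invisible(NULL)
})

#' @describeIn fragmentLadder Accessor for the ion table.
#' @export
ionTable <- function(x) x@ions

#' Predict the CID fragment-ion ladder of an ODN
#'
#' Generates the standard nucleic-acid backbone series used to read
#' sequence out of negative-mode CID spectra.  The `w` series (3'
#' fragments retaining the bridging 5'-phosphate) and the `a-B` series
#' (5' fragments cleaved at the 3' C-O bond with loss of the 3'-terminal
#' nucleobase) are generated by default; `y` (3' fragments with 5'-OH)
#' and `d` (5' fragments with 3'-phosphate) are available on request.
#'
#' Neutral fragment masses are derived from [monoisotopicMass()] of the
#' corresponding sub-sequence plus the series adjustment:
#' `w_i = M(3' i-mer, 5'-phosphate)`, `y_i = M(3' i-mer, 5'-OH)`,
#' `d_i = M(5' i-mer, 3'-phosphate)`, `(a-B)_i = M(5' i-mer, 3'-OH) -
#' H2O - base_i`.
#'
#' @param odn An [ODN-class] of length >= 2.
#' @param charges Integer vector of fragment deprotonation counts.
#' @param series Which series to generate.
#' @param precursorCharge Deprotonation count of the reported precursor
#'   (default 3, the charge state monitored for the released 10-mers).
#' @return A [FragmentIonLadder-class].
#' @examples
#' fragmentLadder(ODN("GGCGTGCTAT"))
#' @export
fragmentLadder <- function(odn, charges = c(1L, 2L),
                           series = c("w", "a-B"), precursorCharge = 3L) {
  stopifnot(is(odn, "ODN"))
  n <- length(odn)
  if (n < 2L) stop("fragment ladder requires length >= 2")
  series <- match.arg(series, c("w", "a-B", "y", "d"), several.ok = TRUE)
  charges <- as.integer(charges)
  stopifnot(all(charges >= 1L))
  chars <- strsplit(odn@bases, "", fixed = TRUE)[[1]]
  rows <- list()
  for (i in seq_len(n - 1L)) {
    neutral <- c()
    if ("w" %in% series)
      neutral["w"] <- monoisotopicMass(
        subODN(odn, n - i + 1L, n, fivePrime = "phosphate",
               threePrime = odn@threePrime))
    if ("y" %in% series)
      neutral["y"] <- monoisotopicMass(
        subODN(odn, n - i + 1L, n, fivePrime = "OH",
               threePrime = odn@threePrime))
    if ("d" %in% series)
      neutral["d"] <- monoisotopicMass(
        subODN(odn, 1L, i, fivePrime = odn@fivePrime,
               threePrime = "phosphate"))
    if ("a-B" %in% series) {
      b <- chars[i]
      baseMass <- .MASS$base[if (b == "X") "T" else b]
      sub <- subODN(odn, 1L, i, fivePrime = odn@fivePrime, threePrime = "OH")
      if (b == "X") {
        # the a-B ion loses the (alkylated) base; remove its shift too
        baseMass <- baseMass + .alkylShift(odn@lesions$alkyl[
          odn@lesions$position == i - 1L])
      }
      neutral["a-B"] <- monoisotopicMass(sub) - .MASS$H2O - unname(baseMass)
    }
    for (s in names(neutral))
      for (z in charges)
        rows[[length(rows) + 1L]] <- data.frame(
          series = s, index = i,
          mz = (neutral[[s]] - z * .MASS$proton) / z,
          charge = z, neutralMass = neutral[[s]],
          stringsAsFactors = FALSE)
  }
  ions <- do.call(rbind, rows)
  rownames(ions) <- NULL
  new("FragmentIonLadder",
      precursorMz = precursorMz(odn, precursorCharge),
      charge = as.integer(precursorCharge), ions = ions)
}
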