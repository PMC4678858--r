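#' Define a sequential digestion/labeling scheme
#'
#' The strand-selective readout rests on the order of operations: first
#' digestion (creates 5'-phosphorylated ends at the first enzyme's cuts),
#' shrimp alkaline phosphatase (removes every accessible 5'-phosphate),
#' T4 polynucleotide kinase with labeled ATP (phosphorylates every free
#' 5'-OH), then the second digestion (creates unlabeled ends).  The net
#' effect: exactly the 5' termini created by the *first* enzyme carry the
#' label.  Amplicon termini are amino-blocked by the PCR primers and are
#' never labeled.
#'
#' Both steps between the digestions are required; omitting either would
#' break the selectivity and is reported as an error.
#'
#' @param first,second Enzyme names, resolved in `enzymes`.
#' @param dephosphorylate,label Must both be `TRUE`; present so a
#'   malformed scheme configuration fails loudly.
#' @param enzymes Named list of [RestrictionEnzyme-class].
#' @return An `AssayScheme` (list with class attribute) with elements
#'   `id`, `first`, `second`, `enzymes`.
#' @examples
#' assayScheme("BbsI", "MluCI")$id  # "BbsI-first"
#' @export
assayScheme <- function(first = "BbsI", second = "MluCI",
                        dephosphorylate = TRUE, label = TRUE,
                        enzymes = defaultEnzymes()) {
  if (!isTRUE(dephosphorylate))
    stop("scheme missing a required step: dephosphorylation (SAP)")
  if (!isTRUE(label))
    stop("scheme missing a required step: 5'-labeling (PNK)")
  for (nm in c(first, second))
    if (!nm %in% names(enzymes))
      stop("enzyme '", nm, "' not found in the enzyme table")
  structure(list(id = paste0(first, "-first"), first = first,
                 second = second, enzymes = enzymes),
            class = "AssayScheme")
}

#' Canonical schemes of the assay
#'
#' `BbsI` first labels the lesion-situated (top) strand's released
#' fragment; `MluCI` first labels the complementary (bottom) strand's.
#'
#' @return A named list of two `AssayScheme`s.
#' @param enzymes Named list of [RestrictionEnzyme-class].
#' @export
canonicalSchemes <- function(enzymes = defaultEnzymes()) {
  list("BbsI-first" = assayScheme("BbsI", "MluCI", enzymes = enzymes),
       "MluCI-first" = assayScheme("MluCI", "BbsI", enzymes = enzymes))
}

#' Sequential digestion with strand-selective label bookkeeping
#'
#' Cuts the duplex with both of the scheme's enzymes and determines which
#' fragment 5' termini carry the post-labeling phosphate: exactly those
#' created by the first digestion (see [assayScheme()]).  Fragments are
#' reported for both strands in 0-based, half-open top-strand
#' coordinates; a bottom-strand fragment's 5' end sits at its `end`
#' coordinate.
#'
#' If the duplex has lost a recognition site (e.g. a large deletion), the
#' corresponding cuts simply do not happen and no labeled short product
#' appears; [isBypassDetectable()] checks for that signature.
#'
#' @param duplex A [DuplexRegion-class].
#' @param scheme An `AssayScheme` from [assayScheme()].
#' @param channel Channel tag copied to the output rows.
#' @param visibleOnly If `TRUE`, return only labeled fragments (the
#'   gel-visible set).
#' @return data.frame with columns `channel`, `scheme`, `strand`,
#'   `start`, `end`, `length`, `sequence` (5'->3' on its own strand) and
#'   `labeled`.
#' @examples
#' frags <- sequentialDigestLabel(competitorAmplicon(),
#'                                assayScheme("BbsI", "MluCI"))
#' subset(frags, labeled)
#' @export
sequentialDigestLabel <- function(duplex, scheme, channel = "lesion",
                                  visibleOnly = FALSE) {
  stopifnot(is(duplex, "DuplexRegion"), inherits(scheme, "AssayScheme"))
  top <- as.character(duplex@top)
  n <- nchar(top)
  s1 <- findSites(duplex, scheme$enzymes[[scheme$first]])
  s2 <- findSites(duplex, scheme$enzymes[[scheme$second]])
  topBounds <- sort(unique(c(0L, s1$topCut, s2$topCut, n)))
  botBounds <- sort(unique(c(0L, s1$bottomCut, s2$bottomCut, n)))
  mkFrags <- function(bounds, strand) {
    a <- bounds[-length(bounds)]
    b <- bounds[-1L]
    keep <- b > a
    a <- a[keep]; b <- b[keep]
    seqs <- substring(top, a + 1L, b)
    if (strand == "bottom")
      seqs <- vapply(seqs, function(s)
        as.character(reverseComplement(ODN(s))), character(1),
        USE.NAMES = FALSE)
    labeled <- if (strand == "top") {
      # a top fragment's 5' end is its start coordinate
      a %in% s1$topCut
    } else {
      # a bottom fragment's 5' end is its end coordinate
      b %in% s1$bottomCut
    }
    data.frame(channel = channel, scheme = scheme$id, strand = strand,
               start = a, end = b, length = b - a, sequence = seqs,
               labeled = labeled, stringsAsFactors = FALSE)
  }
  out <- rbind(mkFrags(topBounds, "top"), mkFrags(botBounds, "bottom"))
  rownames(out) <- NULL
  if (visibleOnly) out <- out[out$labeled, , drop = FALSE]
  out
}

#' Check that a digestion produced the diagnostic labeled product
#'
#' Large deletions that remove the BbsI and/or MluCI recognition site do
#' not release the short restriction fragments the assay reads out, and
#' are scored as lack of replicative bypass.
#'
#' @param fragments Output of [sequentialDigestLabel()].
#' @param maxLength Longest fragment still counted as a diagnostic short
#'   product (the 13-mer competitor standard is the longest expected).
#' @return `TRUE` if any labeled fragment of at most `maxLength` nt is
#'   present; otherwise `FALSE` (non-bypass signature).
#' @export
isBypassDetectable <- function(fragments, maxLength = 13L) {
  any(fragments$labeled & fragments$length <= maxLength)
}
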