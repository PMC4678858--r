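#' GenomeConstruct: insert plus scaffold-defined flanks
#'
#' The assay-relevant slice of the single-stranded shuttle-vector genome:
#' the ligated insert and the vector-derived flanks that the two bridging
#' scaffolds define (plus any user-supplied vector context).  The
#' single-stranded genome beyond scaffold reach is deliberately not
#' reconstructed.
#'
#' @slot insert The ligated insert [ODN-class] (22-mer for the lesion and
#'   control channels).
#' @slot upstreamFlank,downstreamFlank Vector-derived [ODN-class] flanks.
#' @slot channel `"lesion"`, `"control"` or `"competitor"`.
#' @exportClass GenomeConstruct
setClass("GenomeConstruct",
  representation(insert = "ODN", upstreamFlank = "ODN",
                 downstreamFlank = "ODN", channel = "character"))

setValidity("GenomeConstruct", function(object) {
  if (!object@channel %in% c("lesion", "control", "competitor"))
    return("channel must be lesion, control or competitor")
  if (object@channel == "control" && nrow(object@insert@lesions))
    return("a control-channel insert must be lesion-free")
  TRUE
})

setMethod("show", "GenomeConstruct", function(object) {
  cat(sprintf("GenomeConstruct [%s]: %d nt flank + %d nt insert + %d nt flank\n",
              object@channel, length(object@upstreamFlank),
              length(object@insert), length(object@downstreamFlank)))
  cat("  insert: ", as.character(object@insert), "\n")
  invisible(NULL)
})

#' @describeIn assembleConstruct Top-strand sequence of a construct
#'   (flanks plus insert) as a character string.
#' @export
topStrand <- function(construct) {
  paste0(as.character(construct@upstreamFlank),
         as.character(construct@insert),
         as.character(construct@downstreamFlank))
}

# longest exact suffix of `a` equal to a prefix of `b`
.suffixPrefixOverlap <- function(a, b) {
  kmax <- min(nchar(a), nchar(b))
  for (k in seq(kmax, 0L)) {
    if (k == 0L) return(0L)
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k))
      return(k)
  }
}

#' Assemble a genome construct from an insert and two bridging scaffolds
#'
#' Models the scaffold-guided ligation of a 5'-phosphorylated insert into
#' the linearized single-stranded vector.  Each scaffold anneals across
#' one junction, so its reverse complement must read as
#' `vector flank + insert end` with full complementarity over the insert
#' overlap.  The vector-side remainder of each scaffold's reverse
#' complement becomes the corresponding flank; optional `vectorContext`
#' sequence is prepended/appended outside the flanks.
#'
#' @param insert [ODN-class]; must carry a 5'-phosphate (ligatable).
#' @param scaffold1,scaffold2 [ODN-class] or character scaffolds, one per
#'   junction (order-free: which end each bridges is detected).
#' @param vectorContext Optional `list(upstream=, downstream=)` of extra
#'   vector sequence beyond scaffold reach (character).
#' @param channel Channel tag for the construct.
#' @param minOverlap Minimum scaffold/insert complementary overlap (nt)
#'   for a junction to count as bridged.
#' @return A [GenomeConstruct-class].  The junction strings are reported
#'   in attribute `"junctions"`.
#' @examples
#' oli <- assayOligos()
#' ctl <- assembleConstruct(
#'   ODN(lesionFree(ligate(oli$linker10mer,
#'                         setFivePrime(oli$lesion12mer, "phosphate"))),
#'       fivePrime = "phosphate"),
#'   oli$scaffold1, oli$scaffold2, channel = "control")
#' topStrand(ctl)
#' @export
assembleConstruct <- function(insert, scaffold1, scaffold2,
                              vectorContext = list(), channel = "lesion",
                              minOverlap = 4L) {
  stopifnot(is(insert, "ODN"))
  if (!insert@fivePrime %in% c("phosphate", "labeled_phosphate"))
    stop("insert must be 5'-phosphorylated for ligation into the vector")
  asChar <- function(s) if (is(s, "ODN")) as.character(s) else toupper(s)
  ins <- as.character(insert)
  rcs <- vapply(list(scaffold1, scaffold2), function(s)
    as.character(reverseComplement(ODN(asChar(s)))), character(1))
  # which scaffold bridges the 5' junction (its rc ends with an insert
  # prefix) and which the 3' junction (its rc starts with an insert suffix)?
  up5 <- vapply(rcs, .suffixPrefixOverlap, integer(1), b = ins)
  dn3 <- vapply(rcs, function(r) .suffixPrefixOverlap(ins, r), integer(1))
  iUp <- which(up5 >= minOverlap)
  iDn <- which(dn3 >= minOverlap)
  if (length(iUp) != 1L || length(iDn) != 1L || iUp == iDn) {
    junction <- if (length(iUp) != 1L) "upstream (vector | insert 5')"
                else "downstream (insert 3' | vector)"
    stop("scaffold fails to bridge the ", junction, " junction: no ",
         "complementary overlap of at least ", minOverlap, " nt with the insert")
  }
  upFlank <- substr(rcs[iUp], 1L, nchar(rcs[iUp]) - up5[iUp])
  dnFlank <- substr(rcs[iDn], dn3[iDn] + 1L, nchar(rcs[iDn]))
  upCtx <- if (!is.null(vectorContext$upstream))
    toupper(vectorContext$upstream) else ""
  dnCtx <- if (!is.null(vectorContext$downstream))
    toupper(vectorContext$downstream) else ""
  out <- new("GenomeConstruct",
             insert = ODN(ins, lesions = insert@lesions),
             upstreamFlank = ODN(paste0(upCtx, upFlank)),
             downstreamFlank = ODN(paste0(dnFlank, dnCtx)),
             channel = channel)
  attr(out, "junctions") <- c(
    upstream = paste0(substr(upFlank, max(1L, nchar(upFlank) - 8L),
                             nchar(upFlank)), "|",
                      substr(ins, 1L, up5[iUp])),
    downstream = paste0(substr(ins, nchar(ins) - dn3[iDn] + 1L, nchar(ins)),
                        "|", substr(dnFlank, 1L, 8L)))
  out
}

#' DuplexRegion: a double-stranded region in top-strand coordinates
#'
#' The PCR-realized duplex on which digestion operates.  Coordinates are
#' 0-based, half-open, in the frame of the top strand; the bottom strand
#' is the reverse complement of the top.
#'
#' @slot top [ODN-class], written 5'->3'.
#' @slot bottom [ODN-class], the reverse complement of `top` (5'->3' on
#'   its own strand).
#' @exportClass DuplexRegion
setClass("DuplexRegion", representation(top = "ODN", bottom = "ODN"))

setValidity("DuplexRegion", function(object) {
  if (as.character(object@bottom) !=
      as.character(reverseComplement(ODN(as.character(object@top)))))
    return("bottom strand must be the reverse complement of the top strand")
  TRUE
})

#' @rdname DuplexRegion-class
#' @param top [ODN-class] or character top strand.
#' @param fivePrime Terminal chemistry applied to both strands' 5' ends
#'   (PCR primers carry a 5'-amino modifier, so amplicon termini default
#'   to `"amino_blocked"`: the post-labeling step cannot label them).
#' @return A [DuplexRegion-class].
#' @export
duplexRegion <- function(top, fivePrime = "amino_blocked") {
  top <- if (is(top, "ODN")) top else ODN(top)
  topO <- ODN(as.character(top), fivePrime = fivePrime,
              lesions = top@lesions)
  bot <- reverseComplement(ODN(as.character(top)))
  botO <- ODN(as.character(bot), fivePrime = fivePrime,
              lesions = bot@lesions)
  new("DuplexRegion", top = topO, bottom = botO)
}

setMethod("show", "DuplexRegion", function(object) {
  cat(sprintf("DuplexRegion (%d bp)\n", length(object@top)))
  cat("  top:    5'-", as.character(object@top), "-3'\n", sep = "")
  cat("  bottom: 3'-",
      paste(rev(strsplit(as.character(object@bottom), "")[[1]]),
            collapse = ""), "-5'\n", sep = "")
  invisible(NULL)
})

#' @rdname duplexRegion
#' @param x A [DuplexRegion-class].
#' @export
duplexLength <- function(x) length(x@top)

# slide a primer along the template; mismatches are tolerated only within
# the primer's 5'-terminal `maxEndMismatch` bases (PCR extends from an
# annealed 3' end, and the product carries the primer sequence anyway)
.primerSites <- function(template, primer, maxEndMismatch) {
  np <- nchar(primer)
  nt <- nchar(template)
  if (np > nt) return(integer(0))
  pc <- strsplit(primer, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(nt - np + 1L)) {
    wc <- strsplit(substr(template, s, s + np - 1L), "")[[1]]
    mm <- which(wc != pc)
    if (length(mm) <= maxEndMismatch && all(mm <= maxEndMismatch))
      hits <- c(hits, s)
  }
  hits
}

.stripModifier <- function(p) {
  s <- toupper(if (is(p, "ODN")) as.character(p) else p)
  sub("^[^ACGT]+", "", s)
}

#' Realize the PCR amplicon of a construct as a duplex
#'
#' Models high-fidelity PCR as exact duplex realization of the
#' primer-bounded region: the product's top strand is the forward primer
#' sequence, the template interior, then the reverse complement of the
#' reverse primer.  A 5'-amino modifier (any leading non-ACGT code such
#' as `Y`) is stripped from the primers before matching, and the amplicon
#' termini are marked `amino_blocked`.  Each primer must anneal at
#' exactly one site; mismatches are tolerated only among its 5'-terminal
#' `maxEndMismatch` bases.
#'
#' @param construct A [GenomeConstruct-class].
#' @param fwdPrimer,revPrimer Primers ([ODN-class] or character; reverse
#'   primer written 5'->3' on its own strand).
#' @param maxEndMismatch Allowed 5'-terminal mismatch window (nt).
#' @return A [DuplexRegion-class].
#' @examples
#' oli <- assayOligos()
#' ctl <- assembleConstruct(
#'   ODN(lesionFree(ligate(oli$linker10mer,
#'                         setFivePrime(oli$lesion12mer, "phosphate"))),
#'       fivePrime = "phosphate"),
#'   oli$scaffold1, oli$scaffold2,
#'   vectorContext = defaultVectorContext(), channel = "control")
#' extractAmplicon(ctl, oli$fwdPrimer, oli$revPrimer)
#' @export
extractAmplicon <- function(construct, fwdPrimer, revPrimer,
                            maxEndMismatch = 2L) {
  stopifnot(is(construct, "GenomeConstruct"))
  template <- topStrand(construct)
  fwd <- .stripModifier(fwdPrimer)
  rev <- .stripModifier(revPrimer)
  rcRev <- as.character(reverseComplement(ODN(rev)))
  tSearch <- gsub("X", "T", template, fixed = TRUE)
  fHits <- .primerSites(tSearch, fwd, maxEndMismatch)
  # for the reverse primer the 5'-terminal window sits at the right end
  # of its reverse complement
  rcRevCore <- substr(rcRev, 1L, nchar(rcRev) - maxEndMismatch)
  rHits0 <- .primerSites(tSearch, rcRevCore, 0L)
  rHits <- rHits0[rHits0 + nchar(rcRev) - 1L <= nchar(template)]
  if (length(fHits) != 1L)
    stop("forward primer must match the top strand exactly once (found ",
         length(fHits), " sites)")
  if (length(rHits) != 1L)
    stop("reverse primer must match exactly once downstream (found ",
         length(rHits), " sites)")
  if (rHits <= fHits)
    stop("reverse-primer site does not lie downstream of the forward primer")
  interior <- substr(template, fHits + nchar(fwd), rHits - 1L)
  topSeq <- paste0(fwd, interior, rcRev)
  # lesion annotations inside the template interior carry over
  lesAbs <- construct@insert@lesions
  lesAbs$position <- lesAbs$position + length(construct@upstreamFlank)
  keep <- lesAbs$position >= (fHits + nchar(fwd) - 1L) &
          lesAbs$position < (rHits - 1L)
  lesAbs <- lesAbs[keep, , drop = FALSE]
  lesAbs$position <- lesAbs$position - (fHits - 1L)
  topO <- ODN(topSeq, lesions = lesAbs)
  duplexRegion(topO)
}

#' Enumerate the possible replication products of a construct
#'
#' A replication event across the lesion inserts one of the four
#' canonical bases (or, hypothetically, skips one or two positions),
#' so the progeny amplicon carries `M` in `{T, C, A, G}` at the original
#' lesion site on the top strand and the complementary `N` opposite it.
#' Returns the PCR duplex of each outcome.
#'
#' @param construct A [GenomeConstruct-class] with exactly one lesion
#'   position (for a control construct pass `site` explicitly).
#' @param fwdPrimer,revPrimer Primers, as in [extractAmplicon()].
#' @param includeDeletions Also generate the -1 and -2 frameshift
#'   variants at the lesion site (the -2 variant additionally removes the
#'   base 3' of the lesion).
#' @param site 0-based replication-product position within the insert;
#'   defaults to the single lesion position.
#' @return Named list of [DuplexRegion-class] objects
#'   (`M_T, M_C, M_A, M_G`, plus `del1`, `del2` when requested).
#' @export
enumerateOutcomes <- function(construct, fwdPrimer = assayOligos()$fwdPrimer,
                              revPrimer = assayOligos()$revPrimer,
                              includeDeletions = FALSE, site = NULL) {
  stopifnot(is(construct, "GenomeConstruct"))
  if (is.null(site)) {
    pos <- lesionPositions(construct@insert)
    if (length(pos) != 1L)
      stop("construct must have exactly one replication-product position; ",
           "pass `site` for a lesion-free construct")
    site <- pos
  }
  variant <- function(base) {
    ins <- substituteSite(construct@insert, site, base)
    new("GenomeConstruct", insert = ins,
        upstreamFlank = construct@upstreamFlank,
        downstreamFlank = construct@downstreamFlank,
        channel = construct@channel)
  }
  out <- lapply(c(T = "T", C = "C", A = "A", G = "G"), function(b)
    extractAmplicon(variant(b), fwdPrimer, revPrimer))
  names(out) <- paste0("M_", c("T", "C", "A", "G"))
  if (includeDeletions) {
    del1 <- variant("")
    out$del1 <- extractAmplicon(del1, fwdPrimer, revPrimer)
    del2ins <- substituteSite(del1@insert, site, "")
    del2 <- new("GenomeConstruct", insert = del2ins,
                upstreamFlank = construct@upstreamFlank,
                downstreamFlank = construct@downstreamFlank,
                channel = construct@channel)
    out$del2 <- extractAmplicon(del2, fwdPrimer, revPrimer)
  }
  out
}

#' Synthetic competitor amplicon
#'
#' The printed competitor sequences do not by themselves expose the full
#' restriction context of the competitor genome (it comes from a vector
#' construction not reproduced here), so the competitor amplicon is a
#' configurable synthetic fixture.  The default places a BbsI site and
#' the MluCI site around the competitor-specific region so that the
#' BbsI-first scheme releases the 13-nt labeled top fragment
#' `GGCGATAAGCTAT` (the 3' portion of the printed 25-mer competitor
#' insert) and the MluCI-first scheme the 13-nt bottom fragment
#' `AATTATAGCTTAT`, mirroring the 13-mer internal-standard band.
#'
#' @param topSequence Override the fixture's top strand entirely.
#' @return A [DuplexRegion-class].
#' @examples
#' d <- competitorAmplicon()
#' @export
competitorAmplicon <- function(topSequence = NULL) {
  if (is.null(topSequence))
    topSequence <- paste0("CAGCTATGACCATGATTCAGTGTCG",  # synthetic upstream
                          "GAAGAC", "AT",               # BbsI site + spacer
                          "GGCGATAAGCTAT",              # released 13-mer
                          "AATT",                       # MluCI site
                          "CACTGGCCGTCGTTTTACGG")       # synthetic downstream
  duplexRegion(ODN(topSequence))
}

#' Default vector context beyond scaffold reach
#'
#' The reverse-primer site lies outside the scaffold-defined flanks, in
#' vector sequence the assay's printed oligos do not determine.  This
#' synthetic stand-in appends a short spacer followed by the reverse
#' complement of the reverse primer, which is all the pipeline needs for
#' amplicon extraction.
#'
#' @return `list(upstream=, downstream=)` suitable for
#'   [assembleConstruct()]'s `vectorContext`.
#' @export
defaultVectorContext <- function() {
  rcRev <- as.character(reverseComplement(ODN(
    .stripModifier(assayOligos()$revPrimer))))
  list(upstream = "", downstream = paste0("ACGG", rcRev, "TCGCC"))
}
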