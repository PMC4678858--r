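#' The assay's printed oligonucleotides
#'
#' The fixed sequences the experiment is built from: the 12-mer lesion
#' oligo `5'-ATGGCGXGCTAT-3'` (`X` = O4-alkyldT), the 10-mer ligation
#' partner `5'-AGTGGAAGAC-3'` carrying the BbsI site, the two scaffolds
#' bridging the vector junctions, the 25-mer competitor insert, and the
#' PCR primers (5'-amino modifier stripped; their termini are modeled via
#' `amino_blocked` end chemistry).
#'
#' @param alkyl Alkyl group annotated on the lesion 12-mer.
#' @return Named list of [ODN-class] objects.
#' @examples
#' assayOligos("Et")$lesion12mer
#' @export
assayOligos <- function(alkyl = "Me") {
  list(
    lesion12mer  = ODN("ATGGCGXGCTAT", alkyl = alkyl),
    linker10mer  = ODN("AGTGGAAGAC"),
    scaffold1    = ODN("CTTCCACTCACTGAATCATGGTCATAGCTTTC"),
    scaffold2    = ODN("AAAACGACGGCCAGTGAATTATAGC"),
    competitor25mer = ODN("GCAGGATGTCATGGCGATAAGCTAT"),
    fwdPrimer    = ODN("CAGCTATGACCATGATTCAGTGAGTGGA",
                       fivePrime = "amino_blocked"),
    revPrimer    = ODN("TCGGTGCGGGCCTCTTCGCTATTAC",
                       fivePrime = "amino_blocked")
  )
}

#' Build the lesion or control genome construct from the printed oligos
#'
#' Ligates the 10-mer linker to the (5'-phosphorylated) 12-mer lesion
#' oligo and assembles the 22-mer into the scaffold-defined vector
#' context.  The control construct is the same with `X` replaced by `T`.
#'
#' @param channel `"lesion"` or `"control"`.
#' @param alkyl Alkyl group of the lesion.
#' @param vectorContext Vector context, see [assembleConstruct()].
#' @return A [GenomeConstruct-class].
#' @examples
#' defaultConstruct("control")
#' @export
defaultConstruct <- function(channel = c("lesion", "control"),
                             alkyl = "Me",
                             vectorContext = defaultVectorContext()) {
  channel <- match.arg(channel)
  oli <- assayOligos(alkyl)
  insert <- ligate(oli$linker10mer,
                   setFivePrime(oli$lesion12mer, "phosphate"))
  if (channel == "control") insert <- lesionFree(insert)
  assembleConstruct(ODN(insert, fivePrime = "phosphate"),
                    oli$scaffold1, oli$scaffold2,
                    vectorContext = vectorContext, channel = channel)
}

#' Read and write ODNs as FASTA with a lesion sidecar table
#'
#' Plain sequences travel as FASTA; lesion annotations travel in a
#' tab-separated sidecar with columns `sequence_id`, `position` (0-based)
#' and `alkyl_group`, since FASTA has no per-position metadata.
#'
#' @param file FASTA path.
#' @param sidecar Optional sidecar TSV path.
#' @param fivePrime,threePrime End chemistry applied to all records.
#' @return Named list of [ODN-class] objects.
#' @export
readODNFasta <- function(file, sidecar = NULL,
                         fivePrime = "OH", threePrime = "OH") {
  set <- readBStringSet(file)
  side <- if (!is.null(sidecar)) {
    s <- read.delim(sidecar, stringsAsFactors = FALSE)
    need <- c("sequence_id", "position", "alkyl_group")
    if (!all(need %in% names(s)))
      stop("sidecar must have columns: ", paste(need, collapse = ", "))
    s
  }
  out <- lapply(names(set), function(nm) {
    les <- if (!is.null(side) && any(side$sequence_id == nm)) {
      sel <- side[side$sequence_id == nm, , drop = FALSE]
      data.frame(position = as.integer(sel$position),
                 alkyl = sel$alkyl_group, stringsAsFactors = FALSE)
    }
    ODN(as.character(set[[nm]]), fivePrime = fivePrime,
        threePrime = threePrime, lesions = les)
  })
  names(out) <- names(set)
  out
}

#' @rdname readODNFasta
#' @param odns Named list of [ODN-class] objects.
#' @export
writeODNFasta <- function(odns, file, sidecar = NULL) {
  stopifnot(is.list(odns), !is.null(names(odns)))
  set <- BStringSet(vapply(odns, as.character, character(1)))
  writeXStringSet(set, file)
  if (!is.null(sidecar)) {
    rows <- do.call(rbind, lapply(names(odns), function(nm) {
      les <- lesionTable(odns[[nm]])
      if (nrow(les) == 0L) return(NULL)
      data.frame(sequence_id = nm, position = les$position,
                 alkyl_group = les$alkyl, stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
      rows <- data.frame(sequence_id = character(0), position = integer(0),
                         alkyl_group = character(0))
    write.table(rows, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Read and write the band-table TSV dialect
#'
#' One row per band with columns `replicate`, `lane`, `scheme`, `band`,
#' `species`, `channel`, `intensity`.  `readAssayRuns()` reconstructs one
#' [AssayRun-class] per replicate.
#'
#' @param runs List of [AssayRun-class].
#' @param file TSV path.
#' @return `writeAssayRuns()` the path, invisibly; `readAssayRuns()` a
#'   list of [AssayRun-class].
#' @export
writeAssayRuns <- function(runs, file) {
  runs <- .asRunList(runs)
  tab <- do.call(rbind, lapply(runs, function(r)
    cbind(replicate = r@replicate, r@bands)))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeAssayRuns
#' @param rLesion,rControl Mixing ratios to attach (not stored in the
#'   TSV).
#' @export
readAssayRuns <- function(file, rLesion = 1, rControl = 1) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  lapply(split(tab, tab$replicate), function(g)
    assayRun(g$replicate[1], g[, setdiff(names(g), "replicate")],
             rLesion = rLesion, rControl = rControl))
}

#' Write a fragment table
#'
#' @param fragments Output of [sequentialDigestLabel()] (possibly several
#'   rbind-ed calls).
#' @param file TSV path.
#' @export
writeFragments <- function(fragments, file) {
  write.table(fragments, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
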