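#' Candidate released 10-mers for MS identification
#'
#' Replication across the lesion yields four possible bases at the site,
#' so the digestion releases one of four 10-mers per strand:
#' `d(GGCGMGCTAT)` from the lesion-situated (top) strand and
#' `d(AATTATAGCN)` from the complementary (bottom) strand, with `M`/`N`
#' in `{A, T, C, G}`.  The LC-MS/MS workflow dephosphorylates the
#' products, so candidates default to 5'-OH.
#'
#' @param strand `"top"` or `"bottom"`.
#' @param fivePrime Terminal chemistry of the candidates.
#' @return Named list of four [ODN-class] candidates; names are the
#'   variable base (`M` for top, `N` for bottom).
#' @examples
#' names(candidateProducts("top"))
#' @export
candidateProducts <- function(strand = c("top", "bottom"),
                              fivePrime = "OH") {
  strand <- match.arg(strand)
  bases <- c("A", "T", "C", "G")
  seqs <- if (strand == "top") sprintf("GGCG%sGCTAT", bases)
          else sprintf("AATTATAGC%s", bases)
  setNames(lapply(seqs, ODN, fivePrime = fivePrime), bases)
}

#' Identify the base at the lesion site from an ESI peak list
#'
#' Scores each of the four candidate 10-mers of the given strand against
#' a negative-mode peak list: the precursor m/z is checked at the
#' monitored charge state, and the fraction of the candidate's predicted
#' w / a-B fragment ions found within the ppm tolerance is the score
#' (presence/absence only, no intensity weighting -- mirroring manual ion
#' assignment).  Candidates are ranked by precursor match plus fragment
#' score; a tie of the top two within `margin` is flagged as ambiguous.
#'
#' @param peaks data.frame with columns `mz` and `intensity` (a
#'   `PeakList`), e.g. from [generatePeaklist()] or [readPeakList()].
#' @param strand `"top"` or `"bottom"`.
#' @param charge Precursor deprotonation count monitored (default 3,
#'   i.e. `[M-3H]3-`).
#' @param tolPpm Match tolerance in ppm (> 0).
#' @param fragmentCharges Charge states predicted for fragment ions.
#' @param margin Ambiguity margin on the combined score.
#' @return data.frame (class `productMatches`) ordered best-first, with
#'   columns `candidate`, `precursorMatch`, `matchedFragments`,
#'   `predictedFragments`, `score`, `combined`; attribute `"ambiguous"`
#'   says whether the top two are within `margin`.
#' @examples
#' pk <- generatePeaklist(ODN("GGCGCGCTAT"), seed = 1)
#' identifyProduct(pk, "top")[1, "candidate"]  # "C"
#' @export
identifyProduct <- function(peaks, strand = c("top", "bottom"),
                            charge = 3L, tolPpm = 20,
                            fragmentCharges = c(1L, 2L), margin = 0.05) {
  strand <- match.arg(strand)
  if (!is.data.frame(peaks) || !all(c("mz", "intensity") %in% names(peaks)))
    stop("peaks must be a data.frame with columns mz and intensity")
  if (nrow(peaks) == 0L) stop("empty peak list")
  if (!(tolPpm > 0)) stop("tolerance must be > 0 ppm")
  cands <- candidateProducts(strand)
  matchAny <- function(mz) any(abs(peaks$mz - mz) / mz * 1e6 <= tolPpm)
  rows <- lapply(names(cands), function(nm) {
    cand <- cands[[nm]]
    prec <- precursorMz(cand, charge)
    ladder <- fragmentLadder(cand, charges = fragmentCharges,
                             precursorCharge = charge)
    pred <- ionTable(ladder)$mz
    nm_ <- vapply(pred, matchAny, logical(1))
    data.frame(candidate = nm,
               precursorMatch = matchAny(prec),
               matchedFragments = sum(nm_),
               predictedFragments = length(pred),
               score = sum(nm_) / length(pred),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$combined <- out$score + as.numeric(out$precursorMatch)
  out <- out[order(-out$combined, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ambiguous") <- nrow(out) >= 2L &&
    (out$combined[1] - out$combined[2]) < margin
  class(out) <- c("productMatches", class(out))
  out
}

#' Read a peak list
#'
#' Accepts the package's two-column tab-separated dialect (`mz`,
#' `intensity`; header optional) or, when the `mzR` package is available,
#' an mzML file (the base peak list of the first spectrum, or of
#' `scan`).
#'
#' @param path File path.
#' @param scan Spectrum index for mzML input.
#' @return data.frame with columns `mz`, `intensity`.
#' @export
readPeakList <- function(path, scan = 1L) {
  if (!file.exists(path)) stop("peak list not found: '", path, "'")
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    h <- mzR::openMSfile(path)
    on.exit(try(mzR::close(h), silent = TRUE))
    p <- mzR::peaks(h, scan)
    return(data.frame(mz = p[, 1], intensity = p[, 2]))
  }
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("[A-Za-z]", first)
  tab <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("mz", "intensity")
  tab[, c("mz", "intensity")]
}

#' @rdname readPeakList
#' @param peaks data.frame with `mz` and `intensity`.
#' @export
writePeakList <- function(peaks, path) {
  write.table(peaks[, c("mz", "intensity")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
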