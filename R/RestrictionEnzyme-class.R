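#' RestrictionEnzyme: recognition site plus cut geometry
#'
#' Cut offsets are 0-based between-base indices in the coordinate frame
#' of the recognition site's first base, so the model covers both
#' within-site palindromic cutters (EcoRI `G^AATTC`: top 1, bottom 5) and
#' Type IIS enzymes cutting outside the site (BbsI `GAAGAC(2/6)`: top 8,
#' bottom 12).  For a site found in reverse-complement orientation the
#' offsets are mirrored automatically.
#'
#' @slot name Enzyme name.
#' @slot recognition Recognition sequence, written 5'->3'.
#' @slot topCut,bottomCut Signed between-base cut offsets relative to the
#'   recognition start on the strand carrying the recognition sequence.
#' @slot sensitiveToLoss If `TRUE` (all enzymes here), deletion of the
#'   recognition sequence silently abolishes cutting -- the behavior that
#'   makes large deletions score as lack of bypass.
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 topCut = "integer", bottomCut = "integer",
                 sensitiveToLoss = "logical"))

setValidity("RestrictionEnzyme", function(object) {
  if (!nzchar(object@recognition)) return("recognition must be non-empty")
  if (!all(strsplit(object@recognition, "")[[1]] %in% c("A", "C", "G", "T")))
    return("recognition must be an unambiguous A/C/G/T sequence")
  TRUE
})

#' @rdname RestrictionEnzyme-class
#' @param name,recognition,topCut,bottomCut,sensitiveToLoss See slots.
#' @return A [RestrictionEnzyme-class].
#' @examples
#' restrictionEnzyme("BbsI", "GAAGAC", 8, 12)
#' @export
restrictionEnzyme <- function(name, recognition, topCut, bottomCut,
                              sensitiveToLoss = TRUE) {
  new("RestrictionEnzyme", name = name, recognition = toupper(recognition),
      topCut = as.integer(topCut), bottomCut = as.integer(bottomCut),
      sensitiveToLoss = sensitiveToLoss)
}

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s, cuts top %d / bottom %d (from site start)\n",
              object@name, object@recognition, object@topCut, object@bottomCut))
  invisible(NULL)
})

#' Read a restriction-enzyme table
#'
#' Tab-separated file with columns `name`, `recognition`, `top_cut`,
#' `bottom_cut` (between-base offsets from recognition start).  The
#' package ships the three enzymes the assay uses (EcoRI, MluCI, BbsI)
#' with REBASE cut geometry in `extdata/enzymes.tsv`.
#'
#' @param path File path; defaults to the shipped table.
#' @return Named list of [RestrictionEnzyme-class] objects.
#' @examples
#' names(defaultEnzymes())
#' @export
readEnzymeTable <- function(path = system.file("extdata", "enzymes.tsv",
                                               package = "crabReap")) {
  if (!nzchar(path) || !file.exists(path))
    stop("enzyme table not found: '", path, "'")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "top_cut", "bottom_cut")
  if (!all(need %in% names(tab)))
    stop("enzyme table must have columns: ", paste(need, collapse = ", "))
  enz <- lapply(seq_len(nrow(tab)), function(i)
    restrictionEnzyme(tab$name[i], tab$recognition[i],
                      tab$top_cut[i], tab$bottom_cut[i]))
  names(enz) <- tab$name
  enz
}

#' @rdname readEnzymeTable
#' @export
defaultEnzymes <- function() readEnzymeTable()

#' Locate restriction sites on a duplex
#'
#' Finds every occurrence of the recognition sequence on either strand of
#' the duplex (searched on the top strand and its reverse complement; the
#' lesion code `X` is matched as `T`) and resolves both cut positions as
#' between-base indices in the 0-based top-strand frame.  Sites whose cut
#' positions would fall outside the substrate cannot be cut and are
#' dropped.  Palindromic sites are reported once.
#'
#' @param x A [DuplexRegion-class], [ODN-class] or character top strand.
#' @param enzyme A [RestrictionEnzyme-class].
#' @return data.frame with columns `enzyme`, `start` (0-based site
#'   start), `orientation` (`"+"` or `"-"`), `topCut`, `bottomCut`.
#' @examples
#' e <- defaultEnzymes()
#' findSites("AAGAATTCTT", e$EcoRI)
#' @export
findSites <- function(x, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  top <- if (is(x, "DuplexRegion")) as.character(x@top)
         else if (is(x, "ODN")) as.character(x)
         else as.character(x)
  n <- nchar(top)
  subject <- DNAString(gsub("X", "T", top, fixed = TRUE))
  rec <- enzyme@recognition
  len <- nchar(rec)
  hit <- function(pattern, orientation) {
    m <- matchPattern(DNAString(pattern), subject)
    if (length(m) == 0L) return(NULL)
    s <- BiocGenerics::start(m) - 1L
    if (orientation == "+") {
      data.frame(enzyme = enzyme@name, start = s, orientation = "+",
                 topCut = s + enzyme@topCut,
                 bottomCut = s + enzyme@bottomCut,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(enzyme = enzyme@name, start = s, orientation = "-",
                 topCut = s + len - enzyme@bottomCut,
                 bottomCut = s + len - enzyme@topCut,
                 stringsAsFactors = FALSE)
    }
  }
  rc <- as.character(reverseComplement(DNAString(rec)))
  out <- rbind(hit(rec, "+"),
               if (rc != rec) hit(rc, "-"))
  if (is.null(out))
    return(data.frame(enzyme = character(0), start = integer(0),
                      orientation = character(0), topCut = integer(0),
                      bottomCut = integer(0), stringsAsFactors = FALSE))
  # a cut through either strand outside the molecule cannot happen
  out <- out[out$topCut >= 0L & out$topCut <= n &
             out$bottomCut >= 0L & out$bottomCut <= n, , drop = FALSE]
  out <- out[!duplicated(out[c("topCut", "bottomCut")]), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
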