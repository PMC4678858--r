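.END5 <- c("OH", "phosphate", "labeled_phosphate", "amino_blocked")
.END3 <- c("OH", "phosphate")

#' ODN: a single-stranded oligodeoxyribonucleotide
#'
#' An `ODN` holds an ordered run of base codes from `{A,C,G,T}` plus the
#' lesion code `X` (an O4-alkylthymidine), per-position adduct
#' annotations, and the chemistry of both termini.  `X` behaves as `T`
#' for pairing; its monoisotopic mass is the `T` residue plus the alkyl
#' shift from [alkylAdducts()].
#'
#' @slot bases Single character string over `A,C,G,T,X`.
#' @slot lesions data.frame with columns `position` (0-based, must point
#'   at an `X`) and `alkyl` (a code from [alkylAdducts()]).
#' @slot opposite data.frame with the same columns, marking positions
#'   (base `A`) that pair with a lesion on the complementary strand;
#'   populated by [reverseComplement()] so that the operation is an
#'   involution.
#' @slot fivePrime One of `"OH"`, `"phosphate"`, `"labeled_phosphate"`
#'   (a 5'-[32P]-phosphate) or `"amino_blocked"` (5'-amino modifier, as
#'   carried by PCR primers to protect amplicon termini from labeling).
#' @slot threePrime `"OH"` or `"phosphate"`.
#'
#' @seealso [ODN()], [ligate()], [monoisotopicMass()]
#' @exportClass ODN
setClass("ODN",
  representation(bases = "character", lesions = "data.frame",
                 opposite = "data.frame",
                 fivePrime = "character", threePrime = "character"))

.emptyLesions <- function() {
  data.frame(position = integer(0), alkyl = character(0),
             stringsAsFactors = FALSE)
}

setValidity("ODN", function(object) {
  msg <- character(0)
  b <- object@bases
  if (length(b) != 1L || is.na(b) || nchar(b) < 1L)
    return("bases must be a single non-empty string")
  chars <- strsplit(b, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "X")))
    msg <- c(msg, paste0("invalid base code(s): ",
                         paste(unique(setdiff(chars, c("A","C","G","T","X"))),
                               collapse = ", ")))
  les <- object@lesions
  if (!all(c("position", "alkyl") %in% names(les)))
    return("lesions must have columns 'position' and 'alkyl'")
  xpos <- which(chars == "X") - 1L
  if (!setequal(les$position, xpos) || anyDuplicated(les$position))
    msg <- c(msg, "every X position must carry exactly one lesion annotation")
  if (nrow(les) && !all(les$alkyl %in% alkylAdducts()$alkyl))
    msg <- c(msg, "unknown alkyl group in lesion annotation")
  opp <- object@opposite
  if (nrow(opp)) {
    bad <- opp$position < 0L | opp$position >= nchar(b) |
      chars[opp$position + 1L] != "A"
    if (any(bad))
      msg <- c(msg, "opposite-lesion positions must point at an A")
  }
  if (!(length(object@fivePrime) == 1L && object@fivePrime %in% .END5))
    msg <- c(msg, paste0("fivePrime must be one of: ",
                         paste(.END5, collapse = ", ")))
  if (!(length(object@threePrime) == 1L && object@threePrime %in% .END3))
    msg <- c(msg, paste0("threePrime must be one of: ",
                         paste(.END3, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ODN
#'
#' @param seq Character string of base codes (`A,C,G,T,X`), or an `ODN`
#'   (returned unchanged apart from end chemistry overrides).
#' @param fivePrime,threePrime Terminal chemistry; see [ODN-class].
#' @param lesions Either `NULL` (every `X` is annotated with `alkyl`), an
#'   integer vector of 0-based `X` positions, or a data.frame with
#'   columns `position` and `alkyl`.
#' @param alkyl Default alkyl group used when `lesions` carries no
#'   per-position group.
#' @return An [ODN-class] object.
#' @examples
#' ODN("ATGGCGXGCTAT", alkyl = "Et")
#' ODN("AGTGGAAGAC")
#' @export
ODN <- function(seq, fivePrime = "OH", threePrime = "OH",
                lesions = NULL, alkyl = "Me") {
  if (is(seq, "ODN")) {
    seq@fivePrime <- fivePrime
    seq@threePrime <- threePrime
    validObject(seq)
    return(seq)
  }
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || is.na(seq) || nchar(seq) < 1L)
    stop("sequence must be a single non-empty string")
  if (is.null(lesions)) {
    xpos <- as.integer(gregexpr("X", seq, fixed = TRUE)[[1]])
    xpos <- xpos[xpos > 0L] - 1L
    lesions <- data.frame(position = xpos,
                          alkyl = rep(alkyl, length(xpos)),
                          stringsAsFactors = FALSE)
  } else if (is.numeric(lesions)) {
    lesions <- data.frame(position = as.integer(lesions),
                          alkyl = rep(alkyl, length(lesions)),
                          stringsAsFactors = FALSE)
  }
  lesions$position <- as.integer(lesions$position)
  new("ODN", bases = seq, lesions = lesions, opposite = .emptyLesions(),
      fivePrime = fivePrime, threePrime = threePrime)
}

#' @describeIn ODN Number of nucleotides.
#' @param x An `ODN`.
#' @export
setMethod("length", "ODN", function(x) nchar(x@bases))

#' @describeIn ODN The base-code string.
#' @export
setMethod("as.character", "ODN", function(x) x@bases)

setMethod("show", "ODN", function(object) {
  n <- length(object)
  seq <- object@bases
  if (n > 60L) seq <- paste0(substr(seq, 1L, 57L), "...")
  cat(sprintf("ODN (%d nt) 5'-%s-3'  [5': %s, 3': %s]\n",
              n, seq, object@fivePrime, object@threePrime))
  if (nrow(object@lesions))
    cat("  lesions: ",
        paste(sprintf("O4-%sdT@%d", object@lesions$alkyl,
                      object@lesions$position), collapse = ", "), "\n")
  if (nrow(object@opposite))
    cat("  opposite a lesion at position(s): ",
        paste(object@opposite$position, collapse = ", "), "\n")
  invisible(NULL)
})

#' Accessors for ODN terminal chemistry and lesion annotations
#'
#' @param x An [ODN-class].
#' @return `fivePrime()`/`threePrime()` return the end-chemistry string;
#'   `lesionPositions()` the 0-based positions of `X`; `lesionTable()`
#'   the annotation data.frame.
#' @export
fivePrime <- function(x) x@fivePrime

#' @rdname fivePrime
#' @export
threePrime <- function(x) x@threePrime

#' @rdname fivePrime
#' @export
lesionPositions <- function(x) x@lesions$position

#' @rdname fivePrime
#' @export
lesionTable <- function(x) x@lesions

#' @rdname fivePrime
#' @param chemistry New 5' chemistry value.
#' @export
setFivePrime <- function(x, chemistry) {
  x@fivePrime <- chemistry
  validObject(x)
  x
}

#' Reverse complement of an ODN
#'
#' Watson-Crick reverse complement.  The lesion code `X` complements as
#' its parent base `T` (i.e. to `A`); positions opposite a lesion are
#' recorded in the result so that applying the operation twice restores
#' the input, lesion annotations included.  End chemistry swaps 5'/3'
#' roles where representable (a 5'-phosphate becomes a 3'-phosphate; a
#' labeled or blocked 5' end degrades to plain phosphate on the 3' side).
#'
#' @param x An [ODN-class].
#' @return The reverse-complement [ODN-class].
#' @examples
#' as.character(reverseComplement(ODN("GGCGTGCTAT")))  # "ATAGCACGCC"
#' @aliases reverseComplement,ODN-method
#' @export
setMethod("reverseComplement", "ODN", function(x, ...) {
  chars <- strsplit(x@bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  comp <- .complementBase(chars)
  # restore X (with its annotation) at positions that were paired to a
  # lesion, making the operation an involution
  if (nrow(x@opposite))
    comp[x@opposite$position + 1L] <- "X"
  rcBases <- paste(rev(comp), collapse = "")
  mapPos <- function(p) n - 1L - p
  newLesions <- x@opposite
  newLesions$position <- mapPos(newLesions$position)
  newOpp <- x@lesions
  newOpp$position <- mapPos(newOpp$position)
  ord <- order(newLesions$position); newLesions <- newLesions[ord, , drop = FALSE]
  ord <- order(newOpp$position); newOpp <- newOpp[ord, , drop = FALSE]
  rownames(newLesions) <- rownames(newOpp) <- NULL
  flipEnd <- function(e) if (e %in% c("labeled_phosphate", "amino_blocked"))
    "phosphate" else e
  new("ODN", bases = rcBases, lesions = newLesions, opposite = newOpp,
      fivePrime = flipEnd(x@threePrime), threePrime = flipEnd(x@fivePrime))
})

#' Ligate two ODNs
#'
#' Joins `upstream` 3'-OH to `downstream` 5'-phosphate, as T4 DNA ligase
#' does on a nicked duplex.  The junction phosphate becomes an internal
#' phosphodiester; lesion annotations of `downstream` are re-indexed by
#' `length(upstream)`.
#'
#' @param upstream,downstream [ODN-class] objects.  `downstream` must
#'   carry a 5'-phosphate (plain or labeled); `upstream` must end 3'-OH.
#' @return The ligated [ODN-class] with `upstream`'s 5' chemistry and
#'   `downstream`'s 3' chemistry.
#' @examples
#' lig <- ligate(ODN("AGTGGAAGAC"),
#'               ODN("ATGGCGXGCTAT", fivePrime = "phosphate", alkyl = "Me"))
#' length(lig)           # 22
#' lesionPositions(lig)  # 16
#' @export
ligate <- function(upstream, downstream) {
  stopifnot(is(upstream, "ODN"), is(downstream, "ODN"))
  if (!downstream@fivePrime %in% c("phosphate", "labeled_phosphate"))
    stop("downstream ODN is not ligatable: its 5' end is '",
         downstream@fivePrime, "', a 5'-phosphate is required")
  if (upstream@threePrime != "OH")
    stop("upstream ODN must end in 3'-OH to be ligatable")
  nUp <- length(upstream)
  shift <- function(df) { df$position <- df$position + nUp; df }
  lesions <- rbind(upstream@lesions, shift(downstream@lesions))
  opposite <- rbind(upstream@opposite, shift(downstream@opposite))
  rownames(lesions) <- rownames(opposite) <- NULL
  new("ODN", bases = paste0(upstream@bases, downstream@bases),
      lesions = lesions, opposite = opposite,
      fivePrime = upstream@fivePrime, threePrime = downstream@threePrime)
}

#' Extract a sub-sequence of an ODN
#'
#' @param x An [ODN-class].
#' @param start,end 1-based inclusive bounds.
#' @param fivePrime,threePrime Chemistry of the new termini (interior
#'   cuts expose whatever the cutting step leaves; callers decide).
#' @return The sub-[ODN-class]; lesion annotations are subset and
#'   re-indexed.
#' @export
subODN <- function(x, start, end, fivePrime = "OH", threePrime = "OH") {
  stopifnot(is(x, "ODN"), start >= 1L, end <= length(x), start <= end)
  pick <- function(df) {
    df <- df[df$position >= start - 1L & df$position <= end - 1L, , drop = FALSE]
    df$position <- df$position - (start - 1L)
    rownames(df) <- NULL
    df
  }
  new("ODN", bases = substr(x@bases, start, end),
      lesions = pick(x@lesions), opposite = pick(x@opposite),
      fivePrime = fivePrime, threePrime = threePrime)
}

#' Replace the lesion by a canonical base
#'
#' `lesionFree()` converts every `X` to `T` (the lesion-free control
#' sequence); `substituteSite()` writes an arbitrary replication outcome
#' `M` at one position, removing any lesion annotation there.  Progeny
#' and PCR sequences never carry the adduct, only canonical bases.
#'
#' @param x An [ODN-class].
#' @return An [ODN-class] without lesion annotation at the touched
#'   position(s).
#' @export
lesionFree <- function(x) {
  new("ODN", bases = gsub("X", "T", x@bases, fixed = TRUE),
      lesions = .emptyLesions(), opposite = x@opposite,
      fivePrime = x@fivePrime, threePrime = x@threePrime)
}

#' @rdname lesionFree
#' @param position 0-based position to rewrite.
#' @param base Replacement base, one of `A,C,G,T`, or `""` to delete the
#'   position (a -1 frameshift).
#' @export
substituteSite <- function(x, position, base) {
  stopifnot(position >= 0L, position < length(x),
            base %in% c("A", "C", "G", "T", ""))
  chars <- strsplit(x@bases, "", fixed = TRUE)[[1]]
  chars[position + 1L] <- base
  drop <- function(df, del) {
    df <- df[df$position != position, , drop = FALSE]
    if (del) df$position[df$position > position] <-
        df$position[df$position > position] - 1L
    rownames(df) <- NULL
    df
  }
  del <- !nzchar(base)
  new("ODN", bases = paste(chars, collapse = ""),
      lesions = drop(x@lesions, del), opposite = drop(x@opposite, del),
      fivePrime = x@fivePrime, threePrime = x@threePrime)
}
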