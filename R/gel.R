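#' Co-migration rules for native PAGE bands
#'
#' Gel mobility is empirical, so which labeled species share a band is
#' declarative data, not code.  The shipped default
#' (`extdata/comigration.tsv`) encodes the observed behavior on 30%
#' native PAGE: under the BbsI-first (lesion-strand) scheme the 10mer-T
#' and 10mer-C products co-migrate while 10mer-A and 10mer-G resolve;
#' under the MluCI-first (complementary-strand) scheme all four
#' `AATTATAGCN` products resolve, in particular N=A from N=G; the 13-mer
#' competitor standards always run apart from the 10-mers.
#'
#' @param path TSV with columns `scheme`, `species` (fragment sequence)
#'   and `band`; defaults to the shipped table.
#' @return data.frame of rules.
#' @export
comigrationRules <- function(path = system.file("extdata", "comigration.tsv",
                                                package = "crabReap")) {
  if (!nzchar(path) || !file.exists(path))
    stop("co-migration rule table not found: '", path, "'")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("scheme", "species", "band")
  if (!all(need %in% names(tab)))
    stop("co-migration table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Collapse labeled fragments into gel bands
#'
#' Maps each labeled species to its band under the scheme's co-migration
#' rules and aggregates intensities per band.  Species without a rule
#' fall back to a pure length-mobility class (band `"<length>nt"`) unless
#' `strict = TRUE`, in which case they are an error.  Only fragments
#' within the resolved gel window are banded; long cut-off fragments run
#' outside it.
#'
#' @param fragments data.frame with at least `sequence` and `labeled`
#'   columns (as from [sequentialDigestLabel()]); an `intensity` column
#'   (default 1 per row) and a `channel` column are honored.
#' @param scheme Scheme id (e.g. `"BbsI-first"`) or an `AssayScheme`;
#'   defaults to the single scheme present in `fragments`.
#' @param rules Co-migration rule table, see [comigrationRules()].
#' @param strict Error on species without a mobility class.
#' @param gelWindow Fragment lengths resolved on the gel.
#' @return A band table: data.frame with one row per band and columns
#'   `scheme`, `band`, `species` (comma-joined members), `channel`,
#'   `intensity`.
#' @examples
#' frags <- data.frame(sequence = c("GGCGTGCTAT", "GGCGCGCTAT", "GGCGAGCTAT"),
#'                     labeled = TRUE, intensity = c(60, 20, 20))
#' assignBands(frags, "BbsI-first")
#' @export
assignBands <- function(fragments, scheme = NULL, rules = comigrationRules(),
                        strict = FALSE, gelWindow = c(6L, 20L)) {
  if (is.null(scheme)) {
    scheme <- unique(fragments$scheme)
    if (length(scheme) != 1L)
      stop("fragments span several schemes; pass `scheme` explicitly")
  }
  if (inherits(scheme, "AssayScheme")) scheme <- scheme$id
  f <- fragments
  if (is.null(f$labeled)) f$labeled <- TRUE
  if (is.null(f$intensity)) f$intensity <- 1
  if (is.null(f$channel)) f$channel <- "lesion"
  f$length <- nchar(f$sequence)
  f <- f[f$labeled & f$length >= gelWindow[1] & f$length <= gelWindow[2], ,
         drop = FALSE]
  if (nrow(f) == 0L)
    return(data.frame(scheme = character(0), band = character(0),
                      species = character(0), channel = character(0),
                      intensity = numeric(0), stringsAsFactors = FALSE))
  r <- rules[rules$scheme == scheme, , drop = FALSE]
  f$band <- r$band[match(f$sequence, r$species)]
  if (anyNA(f$band)) {
    if (strict)
      stop("no mobility class under the rules for species: ",
           paste(unique(f$sequence[is.na(f$band)]), collapse = ", "))
    f$band[is.na(f$band)] <- paste0(f$length[is.na(f$band)], "nt")
  }
  agg <- lapply(split(f, paste(f$band, f$channel, sep = "\r")), function(g)
    data.frame(scheme = scheme, band = g$band[1],
               species = paste(sort(unique(g$sequence)), collapse = ","),
               channel = g$channel[1],
               intensity = sum(g$intensity), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$band, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' AssayRun: one replicate of the competitive bypass experiment
#'
#' Band tables for both digestion schemes, for the lesion-genome lane
#' (co-transfected with the competitor) and the control-genome lane (also
#' with competitor), plus the transfection mixing ratios.
#'
#' @slot replicate Replicate id.
#' @slot bands data.frame with columns `lane` (`"lesion"`/`"control"`),
#'   `scheme`, `band`, `species`, `channel`
#'   (`"lesion"`/`"control"`/`"competitor"`), `intensity` (>= 0).
#' @slot rLesion,rControl Molar mixing ratios lesion:competitor and
#'   control:competitor used at transfection.
#' @exportClass AssayRun
setClass("AssayRun",
  representation(replicate = "integer", bands = "data.frame",
                 rLesion = "numeric", rControl = "numeric"))

setValidity("AssayRun", function(object) {
  msg <- character(0)
  b <- object@bands
  need <- c("lane", "scheme", "band", "species", "channel", "intensity")
  if (!all(need %in% names(b)))
    return(paste0("bands must have columns: ", paste(need, collapse = ", ")))
  if (any(b$intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (!(object@rLesion > 0 && object@rControl > 0))
    msg <- c(msg, "mixing ratios must be positive")
  for (lane in c("lesion", "control"))
    if (!any(b$lane == lane & b$channel == "competitor"))
      msg <- c(msg, paste0("no competitor band in the ", lane, " lane"))
  if (length(msg)) msg else TRUE
})

#' @rdname AssayRun-class
#' @param replicate,bands,rLesion,rControl See slots.
#' @return An [AssayRun-class].
#' @export
assayRun <- function(replicate, bands, rLesion = 1, rControl = 1) {
  new("AssayRun", replicate = as.integer(replicate), bands = bands,
      rLesion = rLesion, rControl = rControl)
}

setMethod("show", "AssayRun", function(object) {
  cat(sprintf("AssayRun replicate %d: %d bands, ratios %g:1 (lesion), %g:1 (control)\n",
              object@replicate, nrow(object@bands), object@rLesion,
              object@rControl))
  invisible(NULL)
})

.asRunList <- function(runs) {
  if (is(runs, "AssayRun")) return(list(runs))
  stopifnot(is.list(runs), all(vapply(runs, is, logical(1), "AssayRun")))
  runs
}

.speciesLengths <- function(species) {
  vapply(strsplit(species, ",", fixed = TRUE),
         function(s) nchar(s[1]), integer(1))
}

#' Bypass efficiency from replicate band tables
#'
#' Implements the assay's defining ratio-of-ratios,
#' \deqn{BE(\%) = \frac{lesion\ signal / competitor\ signal}
#'                    {control\ signal / competitor\ signal} \times 100,}
#' where the lesion (control) signal is the summed intensity of all
#' 10-mer product bands in that lane and each lane is normalized to its
#' own 13-mer competitor band.  The value is additionally divided by
#' `rLesion / rControl` to correct for the transfection mixing ratios.
#' Within a replicate the ratio is computed per scheme and averaged;
#' across replicates the arithmetic mean and sample SD are reported.
#'
#' @param runs An [AssayRun-class] or list of them (one per replicate).
#' @return List with class `bypassEstimate`: `mean`, `sd`, `perReplicate`
#'   (numeric vector, percent) and `nReplicates`.
#' @examples
#' run <- assayRun(1, data.frame(
#'   lane = c("lesion", "lesion", "control", "control"),
#'   scheme = "BbsI-first",
#'   band = c("10mer-T/C", "13mer", "10mer-T/C", "13mer"),
#'   species = c("GGCGTGCTAT", "GGCGATAAGCTAT", "GGCGTGCTAT", "GGCGATAAGCTAT"),
#'   channel = c("lesion", "competitor", "control", "competitor"),
#'   intensity = c(40, 20, 80, 20)))
#' bypassEfficiency(run)$mean  # 50
#' @export
bypassEfficiency <- function(runs) {
  runs <- .asRunList(runs)
  per <- vapply(runs, function(run) {
    b <- run@bands
    perScheme <- vapply(unique(b$scheme), function(s) {
      bs <- b[b$scheme == s, , drop = FALSE]
      len <- .speciesLengths(bs$species)
      pick <- function(lane, channel, only10 = TRUE)
        sum(bs$intensity[bs$lane == lane & bs$channel == channel &
                         (!only10 | len == 10L)])
      compL <- pick("lesion", "competitor", only10 = FALSE)
      compC <- pick("control", "competitor", only10 = FALSE)
      if (compL <= 0 || compC <= 0)
        stop("competitor signal is zero in replicate ", run@replicate,
             " (scheme ", s, "): bypass efficiency is undefined")
      (pick("lesion", "lesion") / compL) / (pick("control", "control") / compC)
    }, numeric(1))
    mean(perScheme) / (run@rLesion / run@rControl) * 100
  }, numeric(1))
  names(per) <- vapply(runs, function(r) as.character(r@replicate),
                       character(1))
  structure(list(mean = mean(per),
                 sd = if (length(per) > 1L) sd(per) else NA_real_,
                 perReplicate = per, nReplicates = length(per)),
            class = "bypassEstimate")
}

#' @export
print.bypassEstimate <- function(x, ...) {
  cat(sprintf("Bypass efficiency: %.2f%% +/- %s (n = %d)\n", x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.2f%%", x$sd),
              x$nReplicates))
  invisible(x)
}

# base inserted opposite the lesion, read off a released-fragment species
.speciesToM <- function(species, scheme) {
  vapply(strsplit(species, ",", fixed = TRUE), function(members) {
    m <- vapply(members, function(s) {
      if (scheme == "BbsI-first" && nchar(s) == 10L &&
          substr(s, 1, 4) == "GGCG" && substr(s, 6, 10) == "GCTAT")
        substr(s, 5, 5)
      else if (scheme == "MluCI-first" && nchar(s) == 10L &&
               substr(s, 1, 9) == "AATTATAGC")
        unname(.COMPLEMENT[substr(s, 10, 10)])
      else NA_character_
    }, character(1))
    paste(sort(unique(m[!is.na(m)])), collapse = ",")
  }, character(1))
}

# minimize ||A p - y||^2 subject to p >= 0, sum(p) = 1, by enumerating
# support sets (the dimension is 4, so all 15 supports are checked)
.simplexLS <- function(A, y) {
  k <- ncol(A)
  best <- NULL
  bestObj <- Inf
  for (code in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
    As <- A[, S, drop = FALSE]
    m <- length(S)
    kkt <- rbind(cbind(2 * crossprod(As), rep(1, m)),
                 c(rep(1, m), 0))
    rhs <- c(2 * crossprod(As, y), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    p <- sol[seq_len(m)]
    if (any(p < -1e-9)) next
    obj <- sum((As %*% p - y)^2)
    if (obj < bestObj - 1e-12) {
      bestObj <- obj
      full <- numeric(k)
      full[S] <- pmax(p, 0)
      best <- full / sum(full)
    }
  }
  if (is.null(best)) stop("simplex least-squares failed")
  best
}

# solve one replicate's substitution spectrum from both schemes' bands
.solveSpectrum <- function(bands) {
  Ms <- c("T", "C", "A", "G")
  rows <- list(); ys <- numeric(0)
  for (s in unique(bands$scheme)) {
    bs <- bands[bands$scheme == s & bands$lane == "lesion" &
                bands$channel == "lesion", , drop = FALSE]
    mset <- .speciesToM(bs$species, s)
    sub <- bs[nzchar(mset), , drop = FALSE]
    mset <- mset[nzchar(mset)]
    tot <- sum(sub$intensity)
    if (tot <= 0) next
    for (i in seq_len(nrow(sub))) {
      row <- as.numeric(Ms %in% strsplit(mset[i], ",", fixed = TRUE)[[1]])
      rows[[length(rows) + 1L]] <- row
      ys <- c(ys, sub$intensity[i] / tot)
    }
  }
  if (!length(rows))
    stop("all product bands are zero: mutation spectrum is undefined")
  A <- do.call(rbind, rows)
  setNames(.simplexLS(A, ys), paste0("f_", Ms))
}

#' Mutation spectrum at the lesion site
#'
#' Combines the two schemes' band tables into simplex-constrained
#' frequencies of the base `M` inserted opposite the lesion.  The
#' lesion-strand (BbsI-first) scheme resolves `M = A` and `M = G` but
#' merges T with C; the complementary-strand (MluCI-first) scheme
#' resolves `N = A` from `N = G` and thereby splits T from C.  Each
#' band contributes one linear constraint (its share of the scheme's
#' substitution-product signal equals the summed frequency of its member
#' outcomes) and the spectrum is the non-negative least-squares solution
#' on the simplex; with consistent tables the recovery is exact.
#'
#' Frameshift products (9-/8-nt bands), when present, are quantified as a
#' fraction of the total lesion-lane product signal and the substitution
#' spectrum is scaled down accordingly.
#'
#' @param runs An [AssayRun-class] or list of them.
#' @param includeFrameshifts Add `f_del1`/`f_del2` components.
#' @return List with class `mutationSpectrumEstimate`: `spectrum` (mean
#'   frequencies), `sd`, `perReplicate` (matrix), `mutationFrequency`
#'   (list `mean`, `sd`; defined as `1 - f_T`) and `nReplicates`.
#' @export
mutationSpectrum <- function(runs, includeFrameshifts = FALSE) {
  runs <- .asRunList(runs)
  per <- lapply(runs, function(run) {
    b <- run@bands
    if (length(setdiff(c("BbsI-first", "MluCI-first"), unique(b$scheme))))
      stop("both digestion schemes' band tables are required ",
           "(replicate ", run@replicate, ")")
    spec <- .solveSpectrum(b)
    if (includeFrameshifts) {
      les <- b[b$lane == "lesion" & b$channel == "lesion", , drop = FALSE]
      len <- .speciesLengths(les$species)
      tot <- sum(les$intensity)
      d1 <- sum(les$intensity[len == 9L]) / tot
      d2 <- sum(les$intensity[len == 8L]) / tot
      spec <- c(spec * (1 - d1 - d2), f_del1 = d1, f_del2 = d2)
    }
    spec
  })
  mat <- do.call(rbind, per)
  mf <- 1 - mat[, "f_T"]
  structure(list(
    spectrum = colMeans(mat),
    sd = if (nrow(mat) > 1L) apply(mat, 2, sd) else
      setNames(rep(NA_real_, ncol(mat)), colnames(mat)),
    perReplicate = mat,
    mutationFrequency = list(mean = mean(mf),
                             sd = if (length(mf) > 1L) sd(mf) else NA_real_),
    nReplicates = nrow(mat)),
    class = "mutationSpectrumEstimate")
}

#' @export
print.mutationSpectrumEstimate <- function(x, ...) {
  cat("Mutation spectrum at the lesion site (mean over",
      x$nReplicates, "replicates):\n")
  print(round(x$spectrum, 4))
  cat(sprintf("Mutation frequency (1 - f_T): %.4f\n",
              x$mutationFrequency$mean))
  invisible(x)
}

#' Flag putative frameshift products in a band table
#'
#' Labeled product bands of 9 nt (-1) or 8 nt (-2) are reported with
#' their fraction of the table's total signal; fractions below the
#' detection threshold are flagged as not detected (the wet assay reports
#' frameshifts only above its gel detection limit).
#'
#' @param bandTable A band table (one lane/scheme), as from
#'   [assignBands()].
#' @param threshold Detection limit as a fraction of total signal.
#' @return data.frame with columns `band`, `species`, `length`, `shift`
#'   (-1 or -2), `fraction`, `detected`.  Zero rows when no sub-10-mer
#'   band exists.
#' @export
detectFrameshifts <- function(bandTable, threshold = 0.005) {
  len <- .speciesLengths(bandTable$species)
  tot <- sum(bandTable$intensity)
  idx <- which(len %in% c(8L, 9L))
  out <- data.frame(band = bandTable$band[idx],
                    species = bandTable$species[idx],
                    length = len[idx],
                    shift = ifelse(len[idx] == 9L, -1L, -2L),
                    fraction = if (tot > 0) bandTable$intensity[idx] / tot
                               else rep(0, length(idx)),
                    stringsAsFactors = FALSE)
  out$detected <- out$fraction >= threshold
  rownames(out) <- NULL
  out
}
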