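#' GroundTruth: parameters of a synthetic bypass experiment
#'
#' Everything the wet lab would fix by design or that the cell decides:
#' which lesion, how efficiently it is bypassed, the spectrum of bases
#' inserted opposite it, the transfection mixing ratios, the number of
#' replicates and the gel noise level.
#'
#' @slot lesion One of the eight codes in [alkylAdducts()].
#' @slot theta Bypass efficiency in `[0, 1]`.
#' @slot spectrum Named frequencies `f_T, f_C, f_A, f_G` (plus optional
#'   `f_del1`, `f_del2`) on the simplex.
#' @slot rLesion,rControl Molar mixing ratios lesion:competitor and
#'   control:competitor.
#' @slot n Number of replicates (>= 1).
#' @slot sigma Log-scale SD of the multiplicative band noise (>= 0).
#' @slot seed RNG seed.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(lesion = "character", theta = "numeric",
                 spectrum = "numeric", rLesion = "numeric",
                 rControl = "numeric", n = "integer", sigma = "numeric",
                 seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (!object@lesion %in% alkylAdducts()$alkyl)
    msg <- c(msg, "lesion must be one of the eight registry codes")
  if (object@theta < 0 || object@theta > 1)
    msg <- c(msg, "theta must lie in [0, 1]")
  p <- object@spectrum
  if (!all(c("f_T", "f_C", "f_A", "f_G") %in% names(p)))
    msg <- c(msg, "spectrum must name f_T, f_C, f_A, f_G")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "spectrum must be non-negative and sum to 1")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (!(object@rLesion > 0 && object@rControl > 0))
    msg <- c(msg, "mixing ratios must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname GroundTruth-class
#' @param lesion,theta,spectrum,rLesion,rControl,n,sigma,seed See slots.
#' @return A [GroundTruth-class].
#' @examples
#' groundTruth("Et", theta = 0.5,
#'             spectrum = c(f_T = 0.2, f_C = 0.8, f_A = 0, f_G = 0))
#' @export
groundTruth <- function(lesion = "Me", theta = 1,
                        spectrum = c(f_T = 1, f_C = 0, f_A = 0, f_G = 0),
                        rLesion = 2, rControl = 1, n = 3L, sigma = 0.1,
                        seed = 1L) {
  new("GroundTruth", lesion = lesion, theta = theta,
      spectrum = spectrum, rLesion = rLesion, rControl = rControl,
      n = as.integer(n), sigma = sigma, seed = as.integer(seed))
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth O4-%sdT: theta = %.3f, n = %d, sigma = %.2f, ratios %g:1 / %g:1\n",
              object@lesion, object@theta, object@n, object@sigma,
              object@rLesion, object@rControl))
  cat("  spectrum:", paste(sprintf("%s=%.3f", names(object@spectrum),
                                   object@spectrum), collapse = " "), "\n")
  invisible(NULL)
})

# deterministic expected species weights for one lane, per scheme
.expectedSpecies <- function(scheme, weightByM, competitorWeight, channel) {
  Ms <- names(weightByM)
  seqs <- if (scheme == "BbsI-first") {
    c(ifelse(Ms == "del1", "GGCGGCTAT",
      ifelse(Ms == "del2", "GGCGCTAT", sprintf("GGCG%sGCTAT", Ms))))
  } else {
    c(ifelse(Ms == "del1", "AATTATAGC",
      ifelse(Ms == "del2", "AATTATAG",
             sprintf("AATTATAGC%s", unname(.COMPLEMENT[Ms])))))
  }
  compSeq <- if (scheme == "BbsI-first") "GGCGATAAGCTAT" else "AATTATAGCTTAT"
  data.frame(sequence = c(seqs, compSeq), labeled = TRUE,
             intensity = c(unname(weightByM), competitorWeight),
             channel = c(rep(channel, length(Ms)), "competitor"),
             stringsAsFactors = FALSE)
}

#' Generate synthetic replicate assay runs
#'
#' Emulates transfection, in-vivo replication, PCR, digestion/labeling
#' and gel imaging in expectation: in each lane the competitor band is
#' proportional to 1, the lesion-genome product species to
#' `rLesion * theta * p_M`, and the control-genome product to
#' `rControl` (the control is bypassed completely and reads pure T).
#' Species are merged into bands by the co-migration rules, and every
#' band intensity is multiplied by independent lognormal noise
#' `exp(N(0, sigma^2))`.  With the same seed the output is identical.
#'
#' @param gt A [GroundTruth-class].
#' @param rules Co-migration rule table.
#' @param scale Arbitrary intensity unit of the competitor band.
#' @return List of [AssayRun-class], one per replicate.
#' @examples
#' runs <- generateRun(groundTruth("Et", theta = 0.5,
#'   spectrum = c(f_T = 0.2, f_C = 0.8, f_A = 0, f_G = 0), sigma = 0))
#' bypassEfficiency(runs)$mean  # 50
#' @export
generateRun <- function(gt, rules = comigrationRules(), scale = 1000) {
  stopifnot(is(gt, "GroundTruth"))
  validObject(gt)
  set.seed(gt@seed)
  p <- gt@spectrum
  wLesion <- scale * gt@rLesion * gt@theta *
    setNames(p, sub("^f_", "", names(p)))
  wLesion <- wLesion[wLesion > 0]
  wControl <- c(T = scale * gt@rControl)
  lapply(seq_len(gt@n), function(rep) {
    tabs <- lapply(c("BbsI-first", "MluCI-first"), function(s) {
      rbind(
        cbind(lane = "lesion",
              assignBands(.expectedSpecies(s, wLesion, scale, "lesion"),
                          s, rules)),
        cbind(lane = "control",
              assignBands(.expectedSpecies(s, wControl, scale, "control"),
                          s, rules)))
    })
    bands <- do.call(rbind, tabs)
    bands$intensity <- bands$intensity * exp(rnorm(nrow(bands), 0, gt@sigma))
    assayRun(rep, bands, rLesion = gt@rLesion, rControl = gt@rControl)
  })
}

#' Generate a synthetic ESI peak list for a released product
#'
#' Predicts the precursor (at `charge`) and the full w / a-B fragment
#' ladder of the product, perturbs every m/z by Gaussian ppm jitter, and
#' optionally adds uniform decoy peaks.  Seeded and deterministic.
#'
#' @param product An [ODN-class] (e.g. a candidate from
#'   [candidateProducts()]).
#' @param charge Precursor deprotonation count.
#' @param fragmentCharges Fragment charge states.
#' @param ppmJitter SD of the mass error in ppm (>= 0).
#' @param nDecoys Number of uniform decoy peaks to add.
#' @param seed Optional RNG seed.
#' @return data.frame with columns `mz`, `intensity`, sorted by m/z.
#' @examples
#' pk <- generatePeaklist(ODN("AATTATAGCG"), ppmJitter = 5, seed = 7)
#' @export
generatePeaklist <- function(product, charge = 3L,
                             fragmentCharges = c(1L, 2L), ppmJitter = 0,
                             nDecoys = 0L, seed = NULL) {
  stopifnot(is(product, "ODN"), ppmJitter >= 0)
  if (!is.null(seed)) set.seed(seed)
  ladder <- fragmentLadder(product, charges = fragmentCharges,
                           precursorCharge = charge)
  mz <- c(ladder@precursorMz, ionTable(ladder)$mz)
  intensity <- c(100, runif(length(mz) - 1L, 20, 100))
  mz <- mz * (1 + rnorm(length(mz), 0, ppmJitter) * 1e-6)
  if (nDecoys > 0L) {
    mz <- c(mz, runif(nDecoys, min(mz), max(mz)))
    intensity <- c(intensity, runif(nDecoys, 1, 20))
  }
  out <- data.frame(mz = mz, intensity = intensity)
  out[order(out$mz), , drop = FALSE]
}

#' Scenario presets for the eight-lesion panel
#'
#' Reads the shipped `extdata/scenarios.yaml`: one [GroundTruth-class]
#' per lesion, encoding the study design (mixing ratio 2:1 for the
#' straight-chain Me/Et/nPr/nBu lesions, 5:1 for the branched iPr, iBu
#' and the two sec-butyl diastereomers, whose bypass is poor) together
#' with plausible default bypass/spectrum parameters.  The defaults are
#' the generator's study conditions, not fitted values.
#'
#' @param path YAML file of presets.
#' @param seed Seed stored in every preset.
#' @return Named list of [GroundTruth-class] objects.
#' @export
scenarioPresets <- function(path = system.file("extdata", "scenarios.yaml",
                                               package = "crabReap"),
                            seed = 1L) {
  if (!nzchar(path) || !file.exists(path))
    stop("scenario preset file not found: '", path, "'")
  y <- yaml::read_yaml(path)
  out <- lapply(names(y), function(nm) {
    s <- y[[nm]]
    groundTruth(lesion = nm, theta = s$theta,
                spectrum = unlist(s$spectrum),
                rLesion = s$r_lesion, rControl = s$r_control,
                n = if (is.null(s$n)) 3L else s$n,
                sigma = if (is.null(s$sigma)) 0.1 else s$sigma,
                seed = seed)
  })
  names(out) <- names(y)
  out
}
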