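#' @importFrom methods new is validObject setClass setValidity setMethod
#'   setGeneric show slot
NULL

#' RnaAdduct class
#'
#' A 1--3 nucleotide RNA modification carried by a crosslinked peptide,
#' containing at least one 4-thiouridine residue. Construct with
#' \code{\link{rnaAdduct}}.
#'
#' @slot composition Character vector of base codes.
#' @slot modification Neutral modification label.
#' @slot label Human-readable label.
#' @slot precursorMass Neutral mass delta in Da.
#' @name RnaAdduct-class
#' @aliases RnaAdduct
#' @exportClass RnaAdduct
setClass("RnaAdduct",
         representation(composition = "character",
                        modification = "character",
                        label = "character",
                        precursorMass = "numeric"))

setValidity("RnaAdduct", function(object) {
  msgs <- character(0)
  n <- length(object@composition)
  if (n < 1L || n > 3L)
    msgs <- c(msgs, "composition must have 1 to 3 residues")
  if (!"4tU" %in% object@composition)
    msgs <- c(msgs, "composition must contain at least one 4tU residue")
  if (length(object@precursorMass) == 1L && n >= 1L && n <= 3L &&
      "4tU" %in% object@composition) {
    expected <- .adductMass(object@composition, object@modification)
    if (abs(expected - object@precursorMass) > 2e-5)
      msgs <- c(msgs, "precursorMass inconsistent with composition formulas")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RnaAdduct", function(object) {
  cat("RnaAdduct:", object@label,
      sprintf("(%.6f Da)\n", object@precursorMass))
})

#' Spectrum class
#'
#' One MS2 spectrum: a precursor (m/z, charge) and a peak list sorted by
#' m/z. Construct with \code{\link{Spectrum}}.
#'
#' @slot id Spectrum identifier (MGF TITLE).
#' @slot precursorMz Precursor m/z in Th.
#' @slot precursorCharge Integer precursor charge (>= 1).
#' @slot mz Fragment m/z values, sorted ascending.
#' @slot intensity Non-negative intensities, same length as \code{mz}.
#' @name Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
         representation(id = "character",
                        precursorMz = "numeric",
                        precursorCharge = "integer",
                        mz = "numeric",
                        intensity = "numeric"))

setValidity("Spectrum", function(object) {
  msgs <- character(0)
  if (length(object@precursorCharge) != 1L || object@precursorCharge < 1L)
    msgs <- c(msgs, "precursorCharge must be a single integer >= 1")
  if (length(object@precursorMz) != 1L || object@precursorMz <= 0)
    msgs <- c(msgs, "precursorMz must be a single positive number")
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity lengths differ")
  if (length(object@mz) && any(object@mz <= 0))
    msgs <- c(msgs, "all m/z values must be positive")
  if (is.unsorted(object@mz))
    msgs <- c(msgs, "peaks must be sorted by ascending m/z")
  if (length(object@intensity) && any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z on construction.
#'
#' @param id Spectrum identifier.
#' @param precursorMz Precursor m/z (Th).
#' @param precursorCharge Precursor charge (integer >= 1).
#' @param mz,intensity Numeric peak vectors of equal length.
#' @return A \linkS4class{Spectrum}.
#' @export
Spectrum <- function(id, precursorMz, precursorCharge, mz,
                     intensity = rep(1, length(mz))) {
  o <- order(mz)
  new("Spectrum", id = as.character(id),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
}

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", object@id, ":",
      sprintf("precursor %.4f Th (%d+),", object@precursorMz,
              object@precursorCharge),
      length(object@mz), "peaks\n")
})

#' @describeIn Spectrum-class spectrum identifier
#' @param object,x A \code{Spectrum}.
#' @export
spectrumId <- function(object) object@id

#' @describeIn Spectrum-class precursor m/z in Th
#' @export
precursorMz <- function(object) object@precursorMz

#' @describeIn Spectrum-class precursor charge
#' @export
precursorCharge <- function(object) object@precursorCharge

#' @describeIn Spectrum-class two-column peak matrix (mz, intensity)
#' @export
peaks <- function(x) cbind(mz = x@mz, intensity = x@intensity)

#' XlSearchConfig class
#'
#' Parameters of the targeted crosslink search. Construct with
#' \code{\link{xlSearchConfig}}.
#'
#' @slot ms1TolPpm Precursor mass tolerance, ppm.
#' @slot ms2TolPpm Fragment mass tolerance, ppm.
#' @slot maxMissed Maximum missed tryptic cleavages.
#' @slot minLength Minimum peptide length.
#' @slot chargeRange Precursor charges considered (min, max).
#' @slot fragmentChargeMax Maximum fragment-ion charge.
#' @slot maxNeutralLosses Maximum neutral losses per fragment.
#' @slot allowOneDa Whether fragments off by 1 Da also count as matches.
#' @slot fdrThreshold PSM-level FDR acceptance threshold (fraction).
#' @slot maxOxidations Cap on variable Met oxidations per peptide.
#' @name XlSearchConfig-class
#' @exportClass XlSearchConfig
setClass("XlSearchConfig",
         representation(ms1TolPpm = "numeric",
                        ms2TolPpm = "numeric",
                        maxMissed = "integer",
                        minLength = "integer",
                        chargeRange = "integer",
                        fragmentChargeMax = "integer",
                        maxNeutralLosses = "integer",
                        allowOneDa = "logical",
                        fdrThreshold = "numeric",
                        maxOxidations = "integer"))

setValidity("XlSearchConfig", function(object) {
  msgs <- character(0)
  if (object@ms1TolPpm <= 0 || object@ms2TolPpm <= 0)
    msgs <- c(msgs, "tolerances must be positive")
  if (object@fdrThreshold <= 0 || object@fdrThreshold >= 1)
    msgs <- c(msgs, "fdrThreshold must be in (0, 1)")
  if (length(object@chargeRange) != 2L ||
      object@chargeRange[1] < 1L ||
      object@chargeRange[2] < object@chargeRange[1])
    msgs <- c(msgs, "chargeRange must be (min, max) with 1 <= min <= max")
  if (object@minLength < 1L) msgs <- c(msgs, "minLength must be >= 1")
  if (object@maxMissed < 0L) msgs <- c(msgs, "maxMissed must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a crosslink search configuration
#'
#' Defaults follow the targeted search settings used for
#' orbitrap-acquired data: 6 ppm MS1, 20 ppm MS2, trypsin with up to
#' two missed cleavages, minimum peptide length 6, precursor charges
#' 2--7, at most one neutral loss per fragment, 1-Da-off fragment
#' matching on, and a 1\% PSM FDR.
#'
#' @param ms1TolPpm,ms2TolPpm Mass tolerances in ppm.
#' @param maxMissed Maximum missed cleavages.
#' @param minLength Minimum peptide length.
#' @param chargeRange Length-2 integer vector of precursor charges.
#' @param fragmentChargeMax Maximum fragment charge (ion-trap MS2
#'   convention: 2).
#' @param maxNeutralLosses Maximum neutral losses per fragment.
#' @param allowOneDa Count fragment matches off by 1.00335/z Th.
#' @param fdrThreshold FDR acceptance threshold.
#' @param maxOxidations Cap on Met oxidations per peptide.
#' @return An \linkS4class{XlSearchConfig}.
#' @export
xlSearchConfig <- function(ms1TolPpm = 6, ms2TolPpm = 20,
                           maxMissed = 2L, minLength = 6L,
                           chargeRange = c(2L, 7L),
                           fragmentChargeMax = 2L,
                           maxNeutralLosses = 1L,
                           allowOneDa = TRUE,
                           fdrThreshold = 0.01,
                           maxOxidations = 2L) {
  new("XlSearchConfig", ms1TolPpm = ms1TolPpm, ms2TolPpm = ms2TolPpm,
      maxMissed = as.integer(maxMissed), minLength = as.integer(minLength),
      chargeRange = as.integer(chargeRange),
      fragmentChargeMax = as.integer(fragmentChargeMax),
      maxNeutralLosses = as.integer(maxNeutralLosses),
      allowOneDa = allowOneDa, fdrThreshold = fdrThreshold,
      maxOxidations = as.integer(maxOxidations))
}

setMethod("show", "XlSearchConfig", function(object) {
  cat("XlSearchConfig: MS1", object@ms1TolPpm, "ppm; MS2",
      object@ms2TolPpm, "ppm; missed <=", object@maxMissed,
      "; len >=", object@minLength, "; charge",
      paste(object@chargeRange, collapse = "-"),
      "; FDR", object@fdrThreshold, "\n")
})
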