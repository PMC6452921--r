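#' @title In-silico tryptic digestion and decoy databases
#' @name digestion
NULL

## Amino-acid residue formulas (peptide-bonded residues, i.e. minus water).
.RESIDUE_FORMULAS <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.residueMassesEnv <- new.env(parent = emptyenv())

#' Monoisotopic residue masses for the 20 standard amino acids
#'
#' Residue (water-free) masses derived from molecular formulas.
#'
#' @return Named numeric vector of masses in Da.
#' @export
residueMasses <- function() {
  if (is.null(.residueMassesEnv$masses)) {
    .residueMassesEnv$masses <- vapply(.RESIDUE_FORMULAS,
                                       monoisotopicMass, numeric(1))
  }
  .residueMassesEnv$masses
}

#' Common modification mass deltas
#'
#' Carbamidomethyl (iodoacetamide alkylation of Cys, the default fixed
#' modification), carboxymethyl (iodoacetic-acid alkylation, selectable),
#' and Met oxidation -- each derived from its formula.
#'
#' @return Named numeric vector of deltas in Da.
#' @export
modificationDeltas <- function() {
  c(carbamidomethyl = monoisotopicMass("C2H3NO"),
    carboxymethyl = monoisotopicMass("C2H2O2"),
    oxidation = monoisotopicMass("O"))
}

.checkResidues <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(.RESIDUE_FORMULAS))
  if (length(bad))
    stop("non-standard residue '", chars[bad[1]], "' at position ",
         bad[1], " in sequence")
  invisible(chars)
}

#' Neutral monoisotopic mass of a peptide
#'
#' @param sequence Peptide sequence (standard 20-letter alphabet).
#' @param nMod Optional numeric: additional modification mass in Da.
#' @return Neutral mass in Da (residues + water + modifications).
#' @export
peptideMass <- function(sequence, nMod = 0) {
  chars <- .checkResidues(sequence)
  sum(residueMasses()[chars]) + monoisotopicMass("H2O") + nMod
}

#' Tryptic digestion of one protein
#'
#' Cleaves C-terminal to K and R. By default cleavage also occurs before
#' proline (the trypsin\\P convention); set \code{cleaveBeforeProline =
#' FALSE} for classical trypsin specificity.
#'
#' @param sequence Protein sequence, or a one-row protein record
#'   data.frame with columns \code{id}, \code{sequence}, \code{is_decoy}.
#' @param protein Protein identifier (ignored when a record is given).
#' @param maxMissed Maximum internal missed cleavages (default 2).
#' @param minLength Minimum peptide length (default 6).
#' @param cleaveBeforeProline Cleave K/R-P bonds (default TRUE).
#' @param isDecoy Decoy flag propagated to peptides.
#' @return A data.frame with columns \code{sequence}, \code{protein},
#'   \code{start} (1-based), \code{missed_cleavages}, \code{is_decoy}.
#' @examples
#' trypticDigest("MKTAYIAKQR")$sequence
#' @export
trypticDigest <- function(sequence, protein = "protein",
                          maxMissed = 2L, minLength = 6L,
                          cleaveBeforeProline = TRUE,
                          isDecoy = FALSE) {
  if (is.data.frame(sequence)) {
    protein <- sequence$id[1]
    isDecoy <- isTRUE(sequence$is_decoy[1])
    sequence <- sequence$sequence[1]
  }
  chars <- .checkResidues(sequence)
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  if (!cleaveBeforeProline)
    sites <- sites[sites == n | chars[sites + 1L] != "P"]
  bounds <- unique(c(0L, sites[sites < n], n))
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    for (m in 0:maxMissed) {
      j <- i + 1L + m
      if (j > nb) break
      start <- bounds[i] + 1L
      end <- bounds[j]
      if (end - start + 1L < minLength) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(chars[start:end], collapse = ""),
        protein = protein, start = start,
        missed_cleavages = m, is_decoy = isDecoy,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), protein = character(0),
                      start = integer(0), missed_cleavages = integer(0),
                      is_decoy = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Digest a whole protein database
#'
#' @param proteins Protein record data.frame (\code{id},
#'   \code{sequence}, \code{is_decoy}).
#' @inheritParams trypticDigest
#' @return Row-bound digest of every protein.
#' @export
digestDatabase <- function(proteins, maxMissed = 2L, minLength = 6L,
                           cleaveBeforeProline = TRUE) {
  parts <- lapply(seq_len(nrow(proteins)), function(i)
    trypticDigest(proteins$sequence[i], proteins$id[i],
                  maxMissed = maxMissed, minLength = minLength,
                  cleaveBeforeProline = cleaveBeforeProline,
                  isDecoy = isTRUE(proteins$is_decoy[i])))
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Apply fixed and variable modifications to digested peptides
#'
#' The fixed Cys delta is applied to every cysteine. For each peptide,
#' one variant is emitted per subset of oxidized methionines up to
#' \code{maxOxidations}. Neutral masses are (re)computed.
#'
#' @param peptides Digest data.frame from \code{\link{trypticDigest}}.
#' @param fixedCysDelta Fixed Cys modification in Da (default
#'   carbamidomethyl).
#' @param allowMetOxidation Generate oxidized-Met variants.
#' @param maxOxidations Cap on simultaneous oxidations (default 2).
#' @return The peptide table expanded with columns \code{n_ox},
#'   \code{ox_positions} (comma-joined, within-peptide 1-based) and
#'   \code{mass} (neutral Da).
#' @export
applyModifications <- function(peptides,
                               fixedCysDelta = modificationDeltas()[["carbamidomethyl"]],
                               allowMetOxidation = TRUE,
                               maxOxidations = 2L) {
  oxDelta <- modificationDeltas()[["oxidation"]]
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    seqi <- peptides$sequence[i]
    mets <- which(strsplit(seqi, "")[[1]] == "M")
    oxSets <- list(integer(0))
    if (allowMetOxidation && length(mets)) {
      for (k in seq_len(min(length(mets), maxOxidations))) {
        sets <- lapply(utils::combn(seq_along(mets), k,
                                    simplify = FALSE),
                       function(ix) mets[ix])
        oxSets <- c(oxSets, sets)
      }
    }
    base <- peptides[rep(i, length(oxSets)), , drop = FALSE]
    base$n_ox <- vapply(oxSets, length, integer(1))
    base$ox_positions <- vapply(oxSets, paste, character(1), collapse = ",")
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  nCys <- vapply(gregexpr("C", out$sequence, fixed = TRUE),
                 function(m) sum(m > 0), numeric(1))
  out$mass <- vapply(out$sequence, peptideMass, numeric(1),
                     USE.NAMES = FALSE) +
    nCys * fixedCysDelta + out$n_ox * oxDelta
  out
}

## shuffle within tryptic segments, keeping the terminal K/R in place
.shuffleTryptic <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  bounds <- unique(c(0L, sites[sites < n], n))
  for (i in seq_len(length(bounds) - 1L)) {
    start <- bounds[i] + 1L
    end <- bounds[i + 1L]
    last <- if (chars[end] %in% c("K", "R")) end - 1L else end
    if (last > start)
      chars[start:last] <- sample(chars[start:last])
  }
  paste(chars, collapse = "")
}

#' Build a decoy protein database
#'
#' One decoy per target protein, preserving length and amino-acid
#' composition. Reverse mode reverses the sequence; shuffle mode
#' permutes residues within each tryptic segment, keeping the terminal
#' K/R so the decoy peptide mass distribution stays realistic.
#'
#' @param proteins Target protein record data.frame.
#' @param mode \code{"reverse"} or \code{"shuffle"}.
#' @param seed Integer seed (shuffle mode only).
#' @param prefix Identifier prefix marking decoys (default
#'   \code{"REV_"}).
#' @return Protein record data.frame with \code{is_decoy = TRUE}.
#' @export
generateDecoys <- function(proteins, mode = c("reverse", "shuffle"),
                           seed = 1L, prefix = "REV_") {
  mode <- match.arg(mode)
  if (nrow(proteins) == 0L) stop("target database is empty")
  seqs <- if (mode == "reverse") {
    vapply(proteins$sequence, function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
      USE.NAMES = FALSE)
  } else {
    withSeed(seed, vapply(proteins$sequence, .shuffleTryptic,
                          character(1), USE.NAMES = FALSE))
  }
  data.frame(id = paste0(prefix, proteins$id), sequence = seqs,
             is_decoy = TRUE, stringsAsFactors = FALSE)
}

## evaluate expr under a seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
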