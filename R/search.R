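#' @title Targeted crosslink spectrum search
#'
#' @description
#' Matches MS2 spectra against (peptide, RNA adduct) candidates. The
#' crosslinked nucleotide is treated as cleavable: fragment ions that
#' span the crosslinked residue are generated once per retained stub
#' mass (complete loss, the full adduct, and each 4tU-derived stub),
#' while fragments not spanning the site carry no RNA mass. Spectra are
#' searched against targets and decoys together, and the best candidate
#' wins (decoy competition).
#'
#' @name xl-search
NULL

#' XlCandidateIndex class
#'
#' Precursor-mass-sorted index over (peptide, adduct) pairs, queryable
#' by a ppm mass window. Construct with
#' \code{\link{buildCandidateIndex}}.
#'
#' @slot peptides Modified peptide candidate table.
#' @slot adducts Adduct table.
#' @slot mass Sorted combined neutral masses.
#' @slot pepRow,adductRow Parallel row indices into the two tables.
#' @name XlCandidateIndex-class
#' @exportClass XlCandidateIndex
setClass("XlCandidateIndex",
         representation(peptides = "data.frame",
                        adducts = "data.frame",
                        mass = "numeric",
                        pepRow = "integer",
                        adductRow = "integer"))

setMethod("show", "XlCandidateIndex", function(object) {
  cat("XlCandidateIndex:", nrow(object@peptides), "peptides x",
      nrow(object@adducts), "adducts =", length(object@mass),
      "candidates\n")
})

#' Build the (peptide, adduct) candidate index
#'
#' @param peptides Modified peptide table from
#'   \code{\link{applyModifications}} (must carry a \code{mass} column).
#' @param adducts Adduct table from
#'   \code{\link{enumerateTargetedAdducts}}.
#' @return An \linkS4class{XlCandidateIndex}.
#' @export
buildCandidateIndex <- function(peptides, adducts) {
  if (nrow(peptides) == 0L || nrow(adducts) == 0L)
    stop("peptides and adducts must be non-empty")
  np <- nrow(peptides); na <- nrow(adducts)
  pepRow <- rep(seq_len(np), times = na)
  adductRow <- rep(seq_len(na), each = np)
  mass <- peptides$mass[pepRow] + adducts$precursor_mass_da[adductRow]
  o <- order(mass)
  new("XlCandidateIndex", peptides = peptides, adducts = adducts,
      mass = mass[o], pepRow = pepRow[o], adductRow = adductRow[o])
}

#' Query candidates within a ppm window
#'
#' @param index An \linkS4class{XlCandidateIndex}.
#' @param mass Neutral precursor mass in Da.
#' @param ppm Tolerance in ppm.
#' @return A data.frame with columns \code{pepRow}, \code{adductRow},
#'   \code{mass} (possibly 0 rows).
#' @export
queryCandidates <- function(index, mass, ppm) {
  lo <- mass * (1 - ppm * 1e-6)
  hi <- mass * (1 + ppm * 1e-6)
  i1 <- findInterval(lo, index@mass, left.open = TRUE) + 1L
  i2 <- findInterval(hi, index@mass)
  if (i2 < i1)
    return(data.frame(pepRow = integer(0), adductRow = integer(0),
                      mass = numeric(0)))
  sel <- i1:i2
  data.frame(pepRow = index@pepRow[sel], adductRow = index@adductRow[sel],
             mass = index@mass[sel])
}

## per-residue mass vector including fixed Cys and oxidized Met deltas
.modifiedResidueMasses <- function(chars, oxPositions,
                                   fixedCysDelta) {
  r <- residueMasses()[chars]
  r[chars == "C"] <- r[chars == "C"] + fixedCysDelta
  if (length(oxPositions))
    r[oxPositions] <- r[oxPositions] + modificationDeltas()[["oxidation"]]
  unname(r)
}

.parseOxPositions <- function(ox) {
  if (is.null(ox) || is.na(ox) || !nzchar(ox)) integer(0)
  else as.integer(strsplit(ox, ",", fixed = TRUE)[[1]])
}

#' Theoretical fragment ions of a crosslinked peptide
#'
#' Generates b and y ions for fragment charges 1..min(precursor charge,
#' cap). Fragments spanning the crosslinked residue are emitted once per
#' stub mass in \{0 (complete adduct loss), full adduct\} plus the
#' retained-fragment set; other fragments carry no RNA mass. At most one
#' neutral loss (H2O where S/T/E/D present, NH3 where R/K/N/Q present)
#' is applied per fragment.
#'
#' @param sequence Peptide sequence.
#' @param adductMass Neutral adduct precursor mass (Da).
#' @param site Crosslinked residue position within the peptide (1-based).
#' @param config An \linkS4class{XlSearchConfig}.
#' @param precursorCharge Precursor charge (caps fragment charge).
#' @param stubMasses Retained stub masses (default
#'   \code{retentionFragmentSet()$mass}).
#' @param oxPositions Integer positions of oxidized Met (within-peptide).
#' @param fixedCysDelta Fixed Cys modification delta (Da).
#' @return A data.frame with columns \code{series}, \code{index},
#'   \code{charge}, \code{stub}, \code{loss}, \code{mz}. The attribute
#'   \code{"nResidues"} records the peptide length.
#' @export
theoreticalFragments <- function(sequence, adductMass, site,
                                 config = xlSearchConfig(),
                                 precursorCharge = 2L,
                                 stubMasses = retentionFragmentSet()$mass,
                                 oxPositions = integer(0),
                                 fixedCysDelta = modificationDeltas()[["carbamidomethyl"]]) {
  chars <- .checkResidues(sequence)
  n <- length(chars)
  if (site < 1L || site > n) stop("invalid crosslink site: ", site)
  r <- .modifiedResidueMasses(chars, oxPositions, fixedCysDelta)
  prefix <- cumsum(r)
  total <- prefix[n]
  water <- monoisotopicMass("H2O")
  ammonia <- monoisotopicMass("NH3")

  idx <- seq_len(n - 1L)
  ## prefix counts of loss-eligible residues
  h2oRes <- cumsum(chars %in% c("S", "T", "E", "D"))
  nh3Res <- cumsum(chars %in% c("R", "K", "N", "Q"))

  bNeutral <- prefix[idx]
  bSpans <- site <= idx
  bH2O <- h2oRes[idx] > 0
  bNH3 <- nh3Res[idx] > 0
  yNeutral <- total - prefix[n - idx] + water
  ySpans <- site > (n - idx)
  yH2O <- (h2oRes[n] - h2oRes[n - idx]) > 0
  yNH3 <- (nh3Res[n] - nh3Res[n - idx]) > 0

  series <- c(rep("b", n - 1L), rep("y", n - 1L))
  index <- c(idx, idx)
  neutral <- c(bNeutral, yNeutral)
  spans <- c(bSpans, ySpans)
  canH2O <- c(bH2O, yH2O)
  canNH3 <- c(bNH3, yNH3)

  ## expand by stub choice (full adduct may equal a retained stub)
  stubsSpan <- unique(c(0, adductMass, stubMasses))
  nb <- length(series)
  stubCount <- ifelse(spans, length(stubsSpan), 1L)
  rep1 <- rep(seq_len(nb), stubCount)
  stub <- unlist(lapply(seq_len(nb), function(i)
    if (spans[i]) stubsSpan else 0), use.names = FALSE)
  series <- series[rep1]; index <- index[rep1]
  neutral <- neutral[rep1] + stub
  canH2O <- canH2O[rep1]; canNH3 <- canNH3[rep1]

  ## expand by <=1 neutral loss
  if (config@maxNeutralLosses >= 1L) {
    lossCount <- 1L + canH2O + canNH3
    rep2 <- rep(seq_along(series), lossCount)
    loss <- unlist(lapply(seq_along(series), function(i)
      c("none", if (canH2O[i]) "H2O", if (canNH3[i]) "NH3")),
      use.names = FALSE)
    lossDelta <- c(none = 0, H2O = -water, NH3 = -ammonia)[loss]
    series <- series[rep2]; index <- index[rep2]; stub <- stub[rep2]
    neutral <- neutral[rep2] + unname(lossDelta)
  } else {
    loss <- rep("none", length(series))
  }

  ## expand by fragment charge
  zmax <- max(1L, min(config@fragmentChargeMax, precursorCharge))
  zs <- seq_len(zmax)
  m <- length(series)
  rep3 <- rep(seq_len(m), times = length(zs))
  charge <- rep(zs, each = m)
  mz <- (neutral[rep3] + charge * .PROTON_MASS) / charge

  out <- data.frame(series = series[rep3], index = index[rep3],
                    charge = charge, stub = stub[rep3],
                    loss = loss[rep3], mz = mz)
  attr(out, "nResidues") <- n
  out
}

## nearest-peak assignment: for each target m/z, the index of the
## closest peak within relative tolerance, or NA
.nearestPeak <- function(targets, peakMz, tol) {
  i <- findInterval(targets, peakMz)
  np <- length(peakMz)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, np)
  dlo <- abs(peakMz[lo] - targets)
  dhi <- abs(peakMz[hi] - targets)
  best <- ifelse(dlo <= dhi, lo, hi)
  dist <- pmin(dlo, dhi)
  ok <- dist <= targets * tol
  ifelse(ok, best, NA_integer_)
}

#' Score one peptide+adduct+site candidate against a spectrum
#'
#' Matches theoretical fragments to peaks within the MS2 ppm tolerance
#' (optionally also at +/- 1.00335/z Th when 1-Da-off matching is on),
#' with each peak creditable once. The score is the -log10 binomial
#' survival probability of observing at least that many matches among
#' the theoretical fragments, with the per-fragment match probability
#' estimated from the spectrum's peak density and the tolerance window.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param fragments Fragment table from
#'   \code{\link{theoreticalFragments}}.
#' @param config An \linkS4class{XlSearchConfig}.
#' @return A list with \code{score}, \code{coverage} (fraction of
#'   inter-residue bonds supported by a matched fragment),
#'   \code{matched} (distinct matched peaks), \code{matchedStub}
#'   (matched stub-bearing fragments), \code{matchedFrag} (logical
#'   per-fragment match flags, parallel to \code{fragments}) and
#'   \code{matchedExact} (matches within the exact window, ignoring
#'   the 1-Da-off channels).
#' @export
scorePsm <- function(spectrum, fragments, config = xlSearchConfig()) {
  n <- attr(fragments, "nResidues")
  if (length(spectrum@mz) == 0L || nrow(fragments) == 0L)
    return(list(score = 0, coverage = 0, matched = 0L,
                matchedStub = 0L,
                matchedFrag = logical(nrow(fragments))))
  tol <- config@ms2TolPpm * 1e-6
  peakMz <- spectrum@mz

  hit <- .nearestPeak(fragments$mz, peakMz, tol)
  matchedExact <- !is.na(hit)
  if (config@allowOneDa) {
    off <- 1.00335 / fragments$charge
    hitLo <- .nearestPeak(fragments$mz - off, peakMz, tol)
    hitHi <- .nearestPeak(fragments$mz + off, peakMz, tol)
    hit <- ifelse(is.na(hit), ifelse(is.na(hitLo), hitHi, hitLo), hit)
  }
  matchedFrag <- !is.na(hit)
  k <- length(unique(hit[matchedFrag]))
  N <- nrow(fragments)

  span <- max(100, max(peakMz) - min(peakMz))
  nWin <- if (config@allowOneDa) 3 else 1
  width <- 2 * tol * mean(fragments$mz) * nWin
  p <- min(0.5, length(peakMz) * width / span)

  score <- -stats::pbinom(k - 1L, N, p, lower.tail = FALSE,
                          log.p = TRUE) / log(10)
  if (!is.finite(score)) score <- 0

  bonds <- logical(max(n - 1L, 1L))
  mb <- matchedFrag & fragments$series == "b"
  my <- matchedFrag & fragments$series == "y"
  if (n > 1L) {
    bonds[unique(fragments$index[mb])] <- TRUE
    bonds[unique(n - fragments$index[my])] <- TRUE
  }
  list(score = score,
       coverage = if (n > 1L) mean(bonds) else 0,
       matched = as.integer(k),
       matchedStub = as.integer(sum(matchedFrag & fragments$stub > 0)),
       matchedFrag = matchedFrag,
       matchedExact = matchedExact)
}

.emptyPsmTable <- function() {
  data.frame(spectrum_id = character(0), sequence = character(0),
             protein = character(0), start = integer(0),
             missed_cleavages = integer(0), n_ox = integer(0),
             adduct_label = character(0), adduct_mass = numeric(0),
             site = integer(0), site_aa = character(0),
             score = numeric(0), coverage = numeric(0),
             matched = integer(0), matched_stub = integer(0),
             is_decoy = logical(0), stringsAsFactors = FALSE)
}

#' Search one spectrum against the candidate index
#'
#' For every (peptide, adduct) candidate within the MS1 tolerance of the
#' uncharged precursor mass, every crosslink site position is scored and
#' the top-scoring assignment reported. Targets and decoys compete in
#' the same search. The site is reported as undefined (\code{NA}) when
#' no site-determining evidence exists: the best site must strictly
#' out-score every other site and be supported by at least one matched
#' stub-bearing fragment ion.
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param index An \linkS4class{XlCandidateIndex}.
#' @param config An \linkS4class{XlSearchConfig}.
#' @param stubMasses Retained stub masses.
#' @return A list with \code{best} (one-row PSM data.frame, or 0-row if
#'   no candidate lies in the window or the charge is out of range) and
#'   \code{ranked} (per-candidate best assignments, best first).
#' @export
searchSpectrum <- function(spectrum, index, config = xlSearchConfig(),
                           stubMasses = retentionFragmentSet()$mass) {
  empty <- list(best = .emptyPsmTable(), ranked = .emptyPsmTable())
  z <- spectrum@precursorCharge
  if (z < config@chargeRange[1] || z > config@chargeRange[2]) {
    attr(empty$best, "skipped") <- "precursor charge out of range"
    return(empty)
  }
  neutral <- z * spectrum@precursorMz - z * .PROTON_MASS
  cand <- queryCandidates(index, neutral, config@ms1TolPpm)
  if (nrow(cand) == 0L) return(empty)

  rows <- vector("list", nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    pep <- index@peptides[cand$pepRow[ci], ]
    add <- index@adducts[cand$adductRow[ci], ]
    oxPos <- .parseOxPositions(pep$ox_positions)
    nres <- nchar(pep$sequence)
    siteScore <- numeric(nres)
    siteStats <- vector("list", nres)
    siteFrags <- vector("list", nres)
    for (s in seq_len(nres)) {
      fr <- theoreticalFragments(pep$sequence, add$precursor_mass_da, s,
                                 config, z, stubMasses, oxPos)
      st <- scorePsm(spectrum, fr, config)
      siteScore[s] <- st$score
      siteStats[[s]] <- st
      siteFrags[[s]] <- fr
    }
    bestS <- which.max(siteScore)
    st <- siteStats[[bestS]]
    if (nres > 1L) {
      others <- setdiff(seq_len(nres), bestS)
      runnerS <- others[which.max(siteScore[others])]
      ## site-determining evidence: a loss-free stub-bearing ion,
      ## matched in the exact mass window, whose residue span contains
      ## the best site but not the runner-up
      fr <- siteFrags[[bestS]]
      spansAt <- function(s) ifelse(fr$series == "b", s <= fr$index,
                                    s > nres - fr$index)
      determining <- st$matchedExact & fr$stub > 0 &
        fr$loss == "none" & !spansAt(runnerS)
      defined <- (siteScore[bestS] > siteScore[runnerS]) &&
        any(determining)
    } else {
      defined <- st$matchedStub >= 1L
    }
    siteOut <- if (defined) bestS else NA_integer_
    rows[[ci]] <- data.frame(
      spectrum_id = spectrum@id, sequence = pep$sequence,
      protein = pep$protein, start = pep$start,
      missed_cleavages = pep$missed_cleavages, n_ox = pep$n_ox,
      adduct_label = add$label, adduct_mass = add$precursor_mass_da,
      site = siteOut,
      site_aa = if (defined) substr(pep$sequence, bestS, bestS)
                else NA_character_,
      score = siteScore[bestS], coverage = st$coverage,
      matched = st$matched, matched_stub = st$matchedStub,
      is_decoy = isTRUE(pep$is_decoy), stringsAsFactors = FALSE)
  }
  ranked <- do.call(rbind, rows)
  ## deterministic order: score desc, decoys first at ties, then labels
  o <- order(-ranked$score, !ranked$is_decoy, ranked$sequence,
             ranked$adduct_label)
  ranked <- ranked[o, , drop = FALSE]
  rownames(ranked) <- NULL
  list(best = ranked[1, , drop = FALSE], ranked = ranked)
}

#' Search a list of spectra
#'
#' @param spectra List of \linkS4class{Spectrum} objects.
#' @inheritParams searchSpectrum
#' @return PSM table: best hit per spectrum (spectra with no candidate
#'   or out-of-range charge are omitted).
#' @export
searchSpectra <- function(spectra, index, config = xlSearchConfig(),
                          stubMasses = retentionFragmentSet()$mass) {
  res <- lapply(spectra, function(sp)
    searchSpectrum(sp, index, config, stubMasses)$best)
  out <- do.call(rbind, res[vapply(res, nrow, integer(1)) > 0L])
  if (is.null(out)) out <- .emptyPsmTable()
  rownames(out) <- NULL
  out
}
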