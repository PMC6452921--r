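#' @title Ground-truthed synthetic data generators
#'
#' @description
#' Every pipeline stage can be exercised on synthetic input with known
#' truth: random proteomes with tryptic cleavage sites, MS2 spectra of
#' RNA-conjugated peptides with stub fragmentation, noise peaks and
#' ppm-scale mass error, and SILAC peptide tables with planted
#' UV-enriched proteins and intensity-dependent (left-censored)
#' missingness. All generators are pure functions of their
#' configuration and seed.
#'
#' @name synthetic-data
NULL

#' Generate a random proteome
#'
#' Sequences are drawn over the 20-letter alphabet with a configurable
#' combined K/R frequency, so tryptic digestion yields realistic
#' peptide lengths (the default 0.11 gives a mean tryptic peptide of
#' about 9 residues).
#'
#' @param nProteins Number of proteins.
#' @param lengthRange Integer range of protein lengths (uniform draw).
#' @param krFreq Combined frequency of K and R (split evenly).
#' @param seed Integer seed.
#' @return Protein record data.frame (\code{id}, \code{sequence},
#'   \code{is_decoy = FALSE}).
#' @export
generateProteome <- function(nProteins, lengthRange = c(200L, 400L),
                             krFreq = 0.11, seed = 1L) {
  stopifnot(nProteins >= 1L, krFreq > 0, krFreq < 1)
  aa <- names(residueMasses())
  others <- setdiff(aa, c("K", "R"))
  probs <- c(rep(krFreq / 2, 2),
             rep((1 - krFreq) / length(others), length(others)))
  letters <- c("K", "R", others)
  withSeed(seed, {
    lens <- sample(lengthRange[1]:lengthRange[2], nProteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(letters, L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    data.frame(id = sprintf("SYNP%04d", seq_len(nProteins)),
               sequence = seqs, is_decoy = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Spectrum simulation configuration
#'
#' @param detectionProb Probability that a theoretical fragment is
#'   observed (default 1).
#' @param nNoise Number of uniform noise peaks (default 0).
#' @param noiseRange m/z range of noise peaks.
#' @param ppmSd Gaussian mass error scale in ppm (default 0).
#' @param charge Precursor charge; \code{NULL} draws uniformly from
#'   2..7.
#' @param intensityRate Rate of the exponential fragment intensity
#'   model (cosmetic: the default score ignores intensity).
#' @param seed Integer seed.
#' @return A list of class \code{"SpectrumSimConfig"}.
#' @export
spectrumSimConfig <- function(detectionProb = 1, nNoise = 0L,
                              noiseRange = c(100, 1500), ppmSd = 0,
                              charge = NULL, intensityRate = 1,
                              seed = 1L) {
  stopifnot(detectionProb > 0, detectionProb <= 1, nNoise >= 0L)
  structure(list(detectionProb = detectionProb,
                 nNoise = as.integer(nNoise), noiseRange = noiseRange,
                 ppmSd = ppmSd, charge = charge,
                 intensityRate = intensityRate,
                 seed = as.integer(seed)),
            class = "SpectrumSimConfig")
}

#' Simulate an MS2 spectrum of an RNA-conjugated peptide
#'
#' Theoretical fragments of the (peptide, adduct, site) assignment are
#' sampled at the detection probability, perturbed by Gaussian ppm
#' error, and merged with uniform noise peaks. The precursor m/z is
#' consistent with the peptide+adduct mass at the sampled charge.
#'
#' @param sequence Peptide sequence.
#' @param adductMass Neutral adduct mass in Da.
#' @param site Crosslinked residue position (1-based).
#' @param simConfig \code{\link{spectrumSimConfig}}.
#' @param searchConfig \linkS4class{XlSearchConfig} used to generate
#'   fragments.
#' @param id Spectrum identifier.
#' @param oxPositions Oxidized Met positions (within-peptide).
#' @return A list with \code{spectrum} (a \linkS4class{Spectrum}) and
#'   \code{truth} (peptide, adduct mass, site, charge).
#' @export
simulateConjugateSpectrum <- function(sequence, adductMass, site,
                                      simConfig = spectrumSimConfig(),
                                      searchConfig = xlSearchConfig(),
                                      id = "sim", oxPositions = integer(0)) {
  chars <- .checkResidues(sequence)
  pepMass <- sum(.modifiedResidueMasses(
    chars, oxPositions, modificationDeltas()[["carbamidomethyl"]])) +
    monoisotopicMass("H2O")
  withSeed(simConfig$seed, {
    z <- if (is.null(simConfig$charge)) sample(2:7, 1L)
         else as.integer(simConfig$charge)
    fr <- theoreticalFragments(sequence, adductMass, site,
                               searchConfig, z,
                               oxPositions = oxPositions)
    keep <- stats::runif(nrow(fr)) <= simConfig$detectionProb
    mz <- fr$mz[keep]
    mz <- mz * (1 + stats::rnorm(length(mz), 0, simConfig$ppmSd * 1e-6))
    intensity <- stats::rexp(length(mz), simConfig$intensityRate)
    if (simConfig$nNoise > 0L) {
      mz <- c(mz, stats::runif(simConfig$nNoise,
                               simConfig$noiseRange[1],
                               simConfig$noiseRange[2]))
      intensity <- c(intensity,
                     stats::rexp(simConfig$nNoise,
                                 simConfig$intensityRate * 4))
    }
    precMz <- (pepMass + adductMass + z * .PROTON_MASS) / z
    list(spectrum = Spectrum(id, precMz, z, mz, intensity),
         truth = list(sequence = sequence, adductMass = adductMass,
                      site = site, charge = z))
  })
}

#' SILAC table simulation configuration
#'
#' @param nProteins Number of proteins.
#' @param peptideRange Integer range of peptides per protein.
#' @param orientations Per-experiment orientation vector (its length
#'   sets the number of experiments; default three biological
#'   replicates, two forward and one label-swapped).
#' @param binderFraction Fraction of proteins planted as true
#'   UV-enriched RNA binders (default 0.1).
#' @param log2Effect Planted log2 enrichment of binders in the
#'   irradiated channel (default 2, i.e. 4-fold).
#' @param meanLog10Intensity,sdLog10Intensity Log-normal peptide
#'   intensity model (defaults 7 and 0.8 on the log10 scale).
#' @param noiseSdLog2 Per-cell multiplicative noise sd on the log2
#'   scale (default 0.35, i.e. about 27\% CV per channel).
#' @param censorMidpoint,censorSlope Logistic
#'   missing-not-at-random model: a cell of log10 intensity x is
#'   missing with probability \code{plogis(censorSlope *
#'   (censorMidpoint - x))}. A midpoint of \code{-Inf} disables
#'   censoring. Defaults 6 and 2.
#' @param contaminantFraction,decoyFraction Fractions of extra flagged
#'   rows emulating contaminant / decoy peptides (defaults 0.02 each).
#' @param seed Integer seed.
#' @return A list of class \code{"SilacSimConfig"}.
#' @export
silacSimConfig <- function(nProteins = 1000L,
                           peptideRange = c(2L, 8L),
                           orientations = c("forward", "forward",
                                            "reverse"),
                           binderFraction = 0.1, log2Effect = 2,
                           meanLog10Intensity = 7,
                           sdLog10Intensity = 0.8,
                           noiseSdLog2 = 0.35,
                           censorMidpoint = 6, censorSlope = 2,
                           contaminantFraction = 0.02,
                           decoyFraction = 0.02, seed = 1L) {
  stopifnot(binderFraction >= 0, binderFraction <= 1,
            length(orientations) >= 2L)
  structure(list(nProteins = as.integer(nProteins),
                 peptideRange = as.integer(peptideRange),
                 orientations = orientations,
                 binderFraction = binderFraction,
                 log2Effect = log2Effect,
                 meanLog10Intensity = meanLog10Intensity,
                 sdLog10Intensity = sdLog10Intensity,
                 noiseSdLog2 = noiseSdLog2,
                 censorMidpoint = censorMidpoint,
                 censorSlope = censorSlope,
                 contaminantFraction = contaminantFraction,
                 decoyFraction = decoyFraction,
                 seed = as.integer(seed)),
            class = "SilacSimConfig")
}

.randomPeptide <- function(n = 10L) {
  aa <- setdiff(names(residueMasses()), c("K", "R"))
  paste0(paste(sample(aa, n - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Simulate a SILAC peptide evidence table
#'
#' Binder proteins receive the planted log2 enrichment in the
#' irradiated channel of every experiment; peptide intensities are
#' log-normal with multiplicative cell noise; cells go missing with
#' the logistic left-censoring probability. A small number of
#' contaminant- and decoy-flagged rows is appended.
#'
#' @param config \code{\link{silacSimConfig}}.
#' @return A list with \code{table} (peptide evidence table),
#'   \code{design} (\code{\link{silacDesign}}) and \code{truth}
#'   (data.frame \code{protein}, \code{is_binder}, \code{log2_effect}).
#' @export
simulateSilacTable <- function(config = silacSimConfig()) {
  exps <- sprintf("E%d", seq_along(config$orientations))
  design <- silacDesign(exps, config$orientations)
  withSeed(config$seed, {
    nP <- config$nProteins
    prots <- sprintf("PROT%05d", seq_len(nP))
    isBinder <- stats::runif(nP) < config$binderFraction
    effect <- ifelse(isBinder, config$log2Effect, 0)
    nPep <- sample(config$peptideRange[1]:config$peptideRange[2], nP,
                   replace = TRUE)
    protIdx <- rep(seq_len(nP), nPep)
    n <- length(protIdx)
    sequence <- vapply(seq_len(n), function(i)
      .randomPeptide(sample(8:15, 1L)), character(1))
    base <- stats::rnorm(n, config$meanLog10Intensity,
                         config$sdLog10Intensity)
    tab <- data.frame(sequence = sequence, protein = prots[protIdx],
                      reverse = FALSE, contaminant = FALSE,
                      stringsAsFactors = FALSE)
    log2_10 <- log2(10)
    for (ei in seq_along(exps)) {
      e <- exps[ei]
      irradiated <- if (design[[e]] == "forward") "L" else "H"
      for (lab in c("H", "L")) {
        eff <- if (lab == irradiated) effect[protIdx] else 0
        x10 <- base + (eff + stats::rnorm(n, 0, config$noiseSdLog2)) /
          log2_10
        val <- 10^x10
        pMiss <- if (is.infinite(config$censorMidpoint) &&
                     config$censorMidpoint < 0) rep(0, n)
                 else stats::plogis(config$censorSlope *
                                    (config$censorMidpoint - x10))
        val[stats::runif(n) < pMiss] <- NA_real_
        tab[[paste0(lab, ".", e)]] <- val
      }
    }
    ## flagged rows that the filtering step must remove
    nFlag <- round(n * c(config$contaminantFraction,
                         config$decoyFraction))
    if (sum(nFlag) > 0L) {
      flag <- tab[sample.int(n, sum(nFlag), replace = TRUE), ,
                  drop = FALSE]
      flag$contaminant <- rep(c(TRUE, FALSE), nFlag)
      flag$reverse <- rep(c(FALSE, TRUE), nFlag)
      flag$protein <- paste0(ifelse(flag$contaminant, "CON_", "REV_"),
                             flag$protein)
      tab <- rbind(tab, flag)
      rownames(tab) <- NULL
    }
    list(table = tab, design = design,
         truth = data.frame(protein = prots, is_binder = isBinder,
                            log2_effect = effect,
                            stringsAsFactors = FALSE))
  })
}
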