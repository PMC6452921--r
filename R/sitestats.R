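#' @title Crosslink-site statistics
#' @name xl-site-stats
NULL

#' Amino-acid crosslink efficiency
#'
#' Crosslink efficiency of an amino acid is the ratio between its
#' frequency among crosslinked residues and its frequency in all
#' crosslinked peptides. Values above 1 indicate residues crosslinked
#' more often than their availability in the observed peptides would
#' predict (aromatic side chains stack with nucleobases, for example).
#'
#' @param sites Crosslink site data.frame with an \code{amino_acid}
#'   column (one row per unique site).
#' @param peptides Character vector of crosslinked peptide sequences
#'   (each unique peptide once); this is the background pool.
#' @return data.frame with columns \code{amino_acid},
#'   \code{site_freq}, \code{pool_freq}, \code{efficiency}, one row per
#'   amino acid present in the pool (amino acids absent from the pool
#'   are omitted rather than divided by zero).
#' @examples
#' sites <- data.frame(amino_acid = "W")
#' crosslinkEfficiency(sites, "AAAW")
#' @export
crosslinkEfficiency <- function(sites, peptides) {
  if (length(peptides) == 0L || sum(nchar(peptides)) == 0L)
    stop("empty peptide pool")
  if (nrow(sites) == 0L) stop("no crosslink sites supplied")
  poolChars <- unlist(strsplit(peptides, ""), use.names = FALSE)
  poolTab <- table(poolChars)
  poolFreq <- as.numeric(poolTab) / length(poolChars)
  names(poolFreq) <- names(poolTab)
  siteTab <- table(sites$amino_acid)
  aa <- sort(names(poolFreq))
  siteFreq <- as.numeric(siteTab[aa]) / nrow(sites)
  siteFreq[is.na(siteFreq)] <- 0
  data.frame(amino_acid = aa,
             site_freq = siteFreq,
             pool_freq = unname(poolFreq[aa]),
             efficiency = siteFreq / unname(poolFreq[aa]),
             stringsAsFactors = FALSE)
}

#' Missed-cleavage statistics of crosslinked peptides
#'
#' RNA adjacent to a tryptic cleavage site blocks digestion, so
#' crosslinked peptides are expected to retain missed cleavages --
#' especially when the crosslinked residue itself is a lysine or
#' arginine.
#'
#' @param sites Crosslink site data.frame with columns
#'   \code{missed_cleavages} and \code{amino_acid}.
#' @return A list: \code{frac_missed} (fraction of peptides with 1-2
#'   missed cleavages), \code{frac_missed_kr} (same fraction among
#'   K/R-site peptides, \code{NaN} if none), \code{n}, \code{n_kr},
#'   \code{n_missed}, \code{n_missed_kr}.
#' @export
missedCleavageStats <- function(sites) {
  mc <- sites$missed_cleavages >= 1L
  kr <- sites$amino_acid %in% c("K", "R")
  list(frac_missed = mean(mc),
       frac_missed_kr = if (any(kr)) mean(mc[kr]) else NaN,
       n = length(mc), n_kr = sum(kr),
       n_missed = sum(mc), n_missed_kr = sum(mc & kr))
}

#' Abundance-binned enrichment ratios
#'
#' Detected proteins (enriched plus quantified-but-not-enriched) are
#' sorted by abundance and split into equal-count bins; each bin
#' reports its median abundance and the fraction of its proteins that
#' scored as UV-enriched. A declining curve across bins reveals
#' abundance-dependent detection.
#'
#' @param quant data.frame with columns \code{protein} and
#'   \code{enriched} (logical).
#' @param abundances Named numeric vector, protein -> abundance;
#'   required for every included protein.
#' @param exclude Optional character vector of proteins to drop first
#'   (e.g. an annotation class analysed separately).
#' @param nBins Number of bins (default 10). When the protein count is
#'   not divisible, the remainder is spread one-per-bin over the
#'   highest-abundance bins.
#' @return data.frame with columns \code{bin}, \code{n},
#'   \code{n_enriched}, \code{median_abundance}, \code{ratio}
#'   (enriched / (enriched + detected non-enriched)).
#' @export
abundanceBinEnrichment <- function(quant, abundances, exclude = NULL,
                                   nBins = 10L) {
  quant <- quant[!(quant$protein %in% exclude), , drop = FALSE]
  miss <- setdiff(quant$protein, names(abundances))
  if (length(miss))
    stop("no abundance for protein(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  n <- nrow(quant)
  if (n < nBins) stop("fewer proteins (", n, ") than bins (", nBins, ")")
  ab <- unname(abundances[quant$protein])
  o <- order(ab, quant$protein)
  quant <- quant[o, , drop = FALSE]
  ab <- ab[o]
  sizes <- rep(n %/% nBins, nBins)
  r <- n %% nBins
  if (r > 0L) sizes[(nBins - r + 1L):nBins] <- sizes[(nBins - r + 1L):nBins] + 1L
  bin <- rep(seq_len(nBins), sizes)
  out <- data.frame(
    bin = seq_len(nBins),
    n = as.integer(sizes),
    n_enriched = as.integer(tapply(quant$enriched, bin, sum)),
    median_abundance = as.numeric(tapply(ab, bin, stats::median)))
  out$ratio <- out$n_enriched / out$n
  out
}
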