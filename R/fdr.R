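#' @title Target/decoy FDR estimation and PSM deduplication
#' @name fdr
NULL

#' Target/decoy false discovery rate over a PSM list
#'
#' PSMs are sorted by descending match score (decoys ranked above
#' targets at equal score -- the conservative tie-break). The running
#' FDR at each rank is the number of decoy hits divided by the number
#' of target hits so far; q-values are the cumulative minimum of the
#' running FDR taken from the bottom of the list, so they are monotone
#' non-increasing in score. The accepted set is the largest score
#' prefix with q-value at or below the threshold.
#'
#' @param psms PSM data.frame with columns \code{score} and
#'   \code{is_decoy}.
#' @param threshold FDR acceptance threshold (default 0.01).
#' @return A list with \code{psms} (input sorted, plus \code{fdr},
#'   \code{qvalue}, \code{accepted} columns), \code{scoreThreshold}
#'   (lowest accepted score, or \code{NA} if nothing accepted),
#'   \code{nAccepted}, \code{nAcceptedTargets}.
#' @examples
#' psms <- data.frame(score = 6:1,
#'                    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
#' computeFdr(psms)$psms$fdr
#' @export
computeFdr <- function(psms, threshold = 0.01) {
  stopifnot(nrow(psms) >= 1L, is.numeric(psms$score),
            is.logical(psms$is_decoy))
  o <- order(-psms$score, !psms$is_decoy)
  psms <- psms[o, , drop = FALSE]
  nd <- cumsum(psms$is_decoy)
  nt <- cumsum(!psms$is_decoy)
  fdr <- nd / pmax(nt, 1L)
  qvalue <- rev(cummin(rev(fdr)))
  accepted <- qvalue <= threshold
  ## accepted set is a prefix: q-values are monotone non-decreasing down
  ## the list, so the first failure ends the accepted region
  if (any(!accepted)) {
    first <- which(!accepted)[1]
    accepted[first:length(accepted)] <- FALSE
  }
  psms$fdr <- fdr
  psms$qvalue <- qvalue
  psms$accepted <- accepted
  rownames(psms) <- NULL
  list(psms = psms,
       scoreThreshold = if (any(accepted)) min(psms$score[accepted])
                        else NA_real_,
       nAccepted = sum(accepted),
       nAcceptedTargets = sum(accepted & !psms$is_decoy))
}

#' Collapse accepted PSMs into unique crosslink sites
#'
#' Three steps: (1) PSMs with an undefined crosslink site are dropped;
#' (2) PSMs are grouped by (protein, absolute crosslinked residue) and
#' only the highest-scoring PSM per group is kept, so abundant sites
#' observed in many spectra are not over-represented; (3) survivors are
#' grouped by (peptide sequence, adduct) and again the best score wins,
#' reducing over-representation of abundant peptides.
#'
#' @param psms Accepted target PSM data.frame (columns \code{protein},
#'   \code{start}, \code{site}, \code{site_aa}, \code{sequence},
#'   \code{adduct_label}, \code{score}, \code{missed_cleavages}).
#' @return Crosslink site table: one row per unique site with columns
#'   \code{protein}, \code{position} (absolute, 1-based),
#'   \code{amino_acid}, \code{adduct_label}, \code{sequence},
#'   \code{missed_cleavages}, \code{score}; attribute \code{"counts"}
#'   holds unique crosslink / peptide / protein totals.
#' @export
deduplicatePsms <- function(psms) {
  psms <- psms[!is.na(psms$site), , drop = FALSE]
  if (nrow(psms) == 0L) {
    out <- data.frame(protein = character(0), position = integer(0),
                      amino_acid = character(0),
                      adduct_label = character(0),
                      sequence = character(0),
                      missed_cleavages = integer(0), score = numeric(0))
    attr(out, "counts") <- c(crosslinks = 0L, peptides = 0L,
                             proteins = 0L)
    return(out)
  }
  psms$position <- psms$start + psms$site - 1L
  ## deterministic best-per-group: sort by score desc, keep first
  pick <- function(df, key) {
    o <- order(key, -df$score, df$sequence, df$adduct_label)
    df <- df[o, , drop = FALSE]
    df[!duplicated(key[o]), , drop = FALSE]
  }
  psms <- pick(psms, paste(psms$protein, psms$position))
  psms <- pick(psms, paste(psms$sequence, psms$adduct_label))
  out <- data.frame(protein = psms$protein, position = psms$position,
                    amino_acid = psms$site_aa,
                    adduct_label = psms$adduct_label,
                    sequence = psms$sequence,
                    missed_cleavages = psms$missed_cleavages,
                    score = psms$score, stringsAsFactors = FALSE)
  out <- out[order(out$protein, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    crosslinks = nrow(out),
    peptides = length(unique(out$sequence)),
    proteins = length(unique(out$protein)))
  out
}
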