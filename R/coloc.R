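#' @title Phosphosite colocalization permutation test
#'
#' @description
#' Tests whether crosslink sites fall near annotated phosphosites more
#' often than chance. The observed statistic is the split of crosslink
#' sites into "inside" (within the window of any phosphosite on the
#' same protein) and "outside". The expectation is obtained by
#' redrawing each protein's phosphosite positions uniformly at random
#' (without replacement, preserving the per-protein count) and
#' averaging the counts over the shuffles; a chi-square goodness-of-fit
#' over the two categories (1 degree of freedom, no continuity
#' correction) compares observed to expected.
#'
#' @name coloc
NULL

#' Colocalization test parameters
#'
#' @param window Sequence distance in amino acids defining "near a
#'   phosphosite" (default 20).
#' @param nShuffles Number of phosphosite shuffles used to build the
#'   expectation (default 100).
#' @param seed Integer seed for the shuffles.
#' @param styOnly If TRUE, shuffled phosphosites may only land on
#'   serine/threonine/tyrosine residues (default FALSE: any residue).
#' @return A list of class \code{"ColocalizationParams"}.
#' @export
colocalizationParams <- function(window = 20L, nShuffles = 100L,
                                 seed = 1L, styOnly = FALSE) {
  stopifnot(window >= 0L, nShuffles >= 1L)
  structure(list(window = as.integer(window),
                 nShuffles = as.integer(nShuffles),
                 seed = as.integer(seed), styOnly = styOnly),
            class = "ColocalizationParams")
}

## number of sites (integer positions, one protein) within `window` of
## any position in `phos`
.insideCount <- function(sitePos, phos, window) {
  if (length(phos) == 0L || length(sitePos) == 0L) return(0L)
  phos <- sort(phos)
  hi <- findInterval(sitePos + window, phos)
  lo <- findInterval(sitePos - window - 1L, phos)
  sum(hi > lo)
}

#' Phosphosite colocalization of crosslink sites
#'
#' @param sites Crosslink site data.frame with columns \code{protein}
#'   and \code{position}.
#' @param phospho Named list: protein -> integer vector of phosphosite
#'   positions (1-based). Proteins without an entry contribute only to
#'   the "outside" count.
#' @param proteins Protein record data.frame (\code{id},
#'   \code{sequence}) or a named vector of protein lengths; every
#'   site's protein must be covered.
#' @param params \code{\link{colocalizationParams}}.
#' @return A list with \code{observed} (named counts inside/outside),
#'   \code{expected} (mean shuffled counts), \code{statistic}
#'   (chi-square), \code{df} (1), \code{p_value}, \code{nShuffles},
#'   \code{window}.
#' @export
phosphositeColocalization <- function(sites, phospho, proteins,
                                      params = colocalizationParams()) {
  if (is.data.frame(proteins)) {
    lens <- structure(nchar(proteins$sequence), names = proteins$id)
    seqs <- structure(proteins$sequence, names = proteins$id)
  } else {
    lens <- proteins
    seqs <- NULL
  }
  miss <- setdiff(unique(sites$protein), names(lens))
  if (length(miss))
    stop("no sequence length for protein(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  phospho <- phospho[lengths(phospho) > 0L]
  if (length(phospho) == 0L || sum(lengths(phospho)) == 0L)
    stop("no phosphosites supplied")
  bad <- names(phospho)[vapply(names(phospho), function(p)
    p %in% names(lens) && any(phospho[[p]] > lens[[p]]), logical(1))]
  if (length(bad))
    stop("phosphosite beyond protein length for: ",
         paste(bad, collapse = ", "))

  siteByProt <- split(sites$position, sites$protein)
  window <- params$window

  observe <- function(phosList) {
    inside <- 0L
    for (p in names(siteByProt)) {
      inside <- inside +
        .insideCount(siteByProt[[p]], phosList[[p]], window)
    }
    c(inside = inside, outside = nrow(sites) - inside)
  }
  observed <- observe(phospho)

  ## candidate positions per phospho-carrying protein (for shuffles)
  domains <- lapply(names(phospho), function(p) {
    L <- if (p %in% names(lens)) lens[[p]] else max(phospho[[p]])
    if (params$styOnly && !is.null(seqs) && p %in% names(seqs)) {
      pos <- which(strsplit(seqs[[p]], "")[[1]] %in% c("S", "T", "Y"))
      if (length(pos) >= length(phospho[[p]])) pos else seq_len(L)
    } else seq_len(L)
  })
  names(domains) <- names(phospho)

  shuffled <- withSeed(params$seed, {
    vapply(seq_len(params$nShuffles), function(i) {
      perm <- lapply(names(phospho), function(p) {
        dom <- domains[[p]]
        dom[sample.int(length(dom), length(phospho[[p]]))]
      })
      names(perm) <- names(phospho)
      observe(perm)
    }, numeric(2))
  })
  expected <- rowMeans(shuffled)
  if (any(expected == 0))
    stop("expected count of zero in a category; increase nShuffles ",
         "or pool proteins")
  statistic <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
  list(observed = observed, expected = expected,
       statistic = statistic, df = 1L, p_value = p,
       nShuffles = params$nShuffles, window = window)
}
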