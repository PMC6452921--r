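#' @title SILAC UV-enrichment quantification
#'
#' @description
#' Quantifies UV-dependent enrichment of proteins from SILAC peptide
#' intensity tables. Cells with and without UV irradiation are mixed
#' per experiment; in "forward" experiments the light-labelled culture
#' was irradiated, in "reverse" experiments the heavy-labelled one, so
#' the +UV/-UV ratio is light/heavy or heavy/light respectively.
#' Missing intensities are left-censored (low-abundance signals drop
#' below detection), and are imputed from a narrow Gaussian centred at
#' a low quantile of each channel's observed log-intensity
#' distribution.
#'
#' @name silac-quant
NULL

.intensityCols <- function(table) {
  grep("^[HL]\\.", names(table), value = TRUE)
}

#' Experiments present in a peptide table
#'
#' @param table Peptide evidence table (see
#'   \code{\link{readPeptideTable}}).
#' @return Character vector of experiment identifiers.
#' @export
silacExperiments <- function(table) {
  unique(sub("^[HL]\\.", "", .intensityCols(table)))
}

#' Define an experiment design
#'
#' @param experiments Character vector of experiment identifiers.
#' @param orientations \code{"forward"} (light-labelled cells
#'   irradiated) or \code{"reverse"} (heavy-labelled cells irradiated),
#'   one per experiment.
#' @return Named character vector experiment -> orientation.
#' @export
silacDesign <- function(experiments, orientations) {
  stopifnot(length(experiments) == length(orientations))
  orientations <- match.arg(orientations, c("forward", "reverse"),
                            several.ok = TRUE)
  structure(orientations, names = as.character(experiments))
}

.checkDesign <- function(table, design) {
  exps <- silacExperiments(table)
  miss <- setdiff(exps, names(design))
  if (length(miss))
    stop("design lacks orientation for experiment(s): ",
         paste(miss, collapse = ", "))
  exps
}

#' Imputation parameters
#'
#' @param q Quantile of each channel's observed log-intensity
#'   distribution at which imputed draws are centred (default 0.1).
#' @param tuneSigma Width multiplier: the draw standard deviation is
#'   \code{tuneSigma} times the median of per-channel observed log-sd
#'   values. Default 0.01; the yeast UVC-crosslinking preset uses
#'   0.0035 (tighter left-censored draws).
#' @param seed Integer seed for the draws.
#' @return A list of class \code{"ImputationParams"}.
#' @export
imputationParams <- function(q = 0.1, tuneSigma = 0.01, seed = 1L) {
  stopifnot(q > 0, q < 1, tuneSigma > 0)
  structure(list(q = q, tuneSigma = tuneSigma, seed = as.integer(seed)),
            class = "ImputationParams")
}

#' Remove decoy and contaminant peptide rows
#'
#' @param table Peptide evidence table with logical \code{reverse} and
#'   \code{contaminant} columns.
#' @return The table without flagged rows, order preserved.
#' @export
filterPeptideRows <- function(table) {
  need <- c("sequence", "protein", "reverse", "contaminant")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("peptide table missing column(s): ",
         paste(miss, collapse = ", "))
  out <- table[!(table$reverse | table$contaminant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute left-censored missing intensities
#'
#' For each intensity channel (experiment x SILAC label), missing
#' values are drawn independently from a Gaussian centred at the
#' q-quantile of that channel's observed log2-intensity distribution,
#' with standard deviation \code{tuneSigma} times the median of the
#' per-channel observed standard deviations, then back-transformed.
#' Where a peptide was missing in both the +UV and -UV channel of the
#' same experiment, the imputed values are removed again (reset to
#' missing): such a pair carries no ratio information.
#'
#' @param table Filtered peptide evidence table.
#' @param params \code{\link{imputationParams}}.
#' @param design \code{\link{silacDesign}} covering every experiment.
#' @return The table with missing cells imputed; attribute
#'   \code{"imputed"} is a logical matrix (rows x intensity columns)
#'   flagging imputed cells.
#' @export
imputeMissing <- function(table, params = imputationParams(),
                          design) {
  .checkDesign(table, design)
  cols <- .intensityCols(table)
  exps <- silacExperiments(table)
  logI <- lapply(cols, function(cn) log2(table[[cn]]))
  names(logI) <- cols
  obsSd <- vapply(logI, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else stats::sd(v)
  }, numeric(1))
  if (anyNA(obsSd))
    stop("channel with no observed values: ",
         paste(cols[is.na(obsSd)], collapse = ", "))
  sigma <- params$tuneSigma * stats::median(obsSd)
  isMissing <- function(v) !is.finite(v) | v == 0
  bothMissing <- lapply(exps, function(e)
    isMissing(table[[paste0("H.", e)]]) &
      isMissing(table[[paste0("L.", e)]]))
  names(bothMissing) <- exps

  imputed <- matrix(FALSE, nrow(table), length(cols),
                    dimnames = list(NULL, cols))
  out <- table
  n <- nrow(table)
  ## standard-normal draws keyed by (row, experiment, channel role):
  ## the irradiated channel of an experiment uses zIrr, the control
  ## channel zCtl. Because the role -- not the SILAC label -- selects
  ## the draw, swapping every label and flipping the orientation
  ## reproduces identical imputed values (label-swap invariance).
  draws <- withSeed(params$seed, list(
    zIrr = matrix(stats::rnorm(n * length(exps)), n, length(exps),
                  dimnames = list(NULL, exps)),
    zCtl = matrix(stats::rnorm(n * length(exps)), n, length(exps),
                  dimnames = list(NULL, exps))))
  for (e in exps) {
    irrLabel <- if (design[[e]] == "forward") "L" else "H"
    for (lab in c("H", "L")) {
      cn <- paste0(lab, ".", e)
      v <- out[[cn]]
      missIdx <- which(!is.finite(v) | v == 0)
      if (!length(missIdx)) next
      obs <- log2(v[is.finite(v) & v > 0])
      mu <- stats::quantile(obs, params$q, names = FALSE)
      z <- if (lab == irrLabel) draws$zIrr[missIdx, e]
           else draws$zCtl[missIdx, e]
      v[missIdx] <- 2^(mu + sigma * z)
      out[[cn]] <- v
      imputed[missIdx, cn] <- TRUE
    }
  }
  for (e in exps) {
    both <- bothMissing[[e]]
    for (cn in c(paste0("H.", e), paste0("L.", e))) {
      out[[cn]][both] <- NA_real_
      imputed[both, cn] <- FALSE
    }
  }
  attr(out, "imputed") <- imputed
  out
}

#' Per-peptide +UV/-UV ratios
#'
#' The numerator is always the irradiated channel: light/heavy in
#' forward experiments, heavy/light in reverse experiments. Ratios are
#' undefined (\code{NA}) where either channel is missing or the
#' denominator is zero.
#'
#' @param table (Imputed) peptide evidence table.
#' @param design \code{\link{silacDesign}}.
#' @return data.frame with \code{sequence}, \code{protein} and one
#'   ratio column per experiment (named by experiment).
#' @export
peptideRatios <- function(table, design) {
  exps <- .checkDesign(table, design)
  out <- table[, c("sequence", "protein"), drop = FALSE]
  for (e in exps) {
    h <- table[[paste0("H.", e)]]
    l <- table[[paste0("L.", e)]]
    r <- if (design[[e]] == "forward") l / h else h / l
    r[!is.finite(r)] <- NA_real_
    out[[e]] <- r
  }
  rownames(out) <- NULL
  out
}

#' Aggregate peptide ratios to protein level
#'
#' Per (protein, experiment): the median of defined peptide ratios,
#' log2-transformed, with the contributing peptide count recorded. The
#' protein identifier is the leading razor protein of each peptide.
#'
#' @param pepRatios Output of \code{\link{peptideRatios}}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} (rows =
#'   proteins, columns = experiments) with assays \code{log2ratio} and
#'   \code{npep}.
#' @export
aggregateProteinRatios <- function(pepRatios) {
  exps <- setdiff(names(pepRatios), c("sequence", "protein"))
  prots <- sort(unique(pepRatios$protein))
  grp <- match(pepRatios$protein, prots)
  log2ratio <- matrix(NA_real_, length(prots), length(exps),
                      dimnames = list(prots, exps))
  npep <- matrix(0L, length(prots), length(exps),
                 dimnames = list(prots, exps))
  for (e in exps) {
    r <- pepRatios[[e]]
    ok <- !is.na(r)
    med <- tapply(r[ok], grp[ok], stats::median)
    cnt <- tapply(r[ok], grp[ok], length)
    idx <- as.integer(names(med))
    log2ratio[idx, e] <- log2(as.numeric(med))
    npep[idx, e] <- as.integer(cnt)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = log2ratio, npep = npep))
}

#' Filter proteins by peptide support
#'
#' Keeps proteins quantified with at least \code{minPeptides} peptides
#' in at least \code{minExperiments} experiments.
#'
#' @param se SummarizedExperiment from
#'   \code{\link{aggregateProteinRatios}}.
#' @param minPeptides,minExperiments Integer thresholds (defaults 2, 2).
#' @return The filtered SummarizedExperiment.
#' @export
filterProteins <- function(se, minPeptides = 2L, minExperiments = 2L) {
  npep <- SummarizedExperiment::assay(se, "npep")
  keep <- rowSums(npep >= minPeptides) >= minExperiments
  se[keep, ]
}

#' Run the full enrichment pipeline on a peptide table
#'
#' Convenience wrapper: row filtering, imputation, per-peptide ratios,
#' protein aggregation, the peptide/experiment support filter, and the
#' moderated test.
#'
#' @param table Peptide evidence table.
#' @param design \code{\link{silacDesign}}.
#' @param params \code{\link{imputationParams}}.
#' @param minPeptides,minExperiments Support thresholds.
#' @return \code{\link{moderatedTest}} result data.frame.
#' @export
silacEnrichment <- function(table, design, params = imputationParams(),
                            minPeptides = 2L, minExperiments = 2L) {
  tab <- filterPeptideRows(table)
  tab <- imputeMissing(tab, params, design)
  pr <- peptideRatios(tab, design)
  se <- aggregateProteinRatios(pr)
  se <- filterProteins(se, minPeptides, minExperiments)
  moderatedTest(se)
}
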