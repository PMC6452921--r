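#' @title Empirical-Bayes moderated one-sample t-test
#'
#' @description
#' Protein-level log2 ratios are tested against zero with a moderated
#' one-sample t-test: per-protein sample variances are shrunk towards a
#' prior by empirical Bayes. Writing \eqn{s_g^2} for the sample variance
#' of protein g on \eqn{d_g} degrees of freedom, the posterior variance
#' is \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}, the
#' moderated statistic is \eqn{t_g = \bar x_g / (\tilde s_g/\sqrt{n_g})}
#' on \eqn{d_0 + d_g} degrees of freedom, and the hyperparameters
#' \eqn{(d_0, s_0^2)} are estimated by moment matching on the
#' distribution of log sample variances across proteins.
#'
#' @name moderated-test
NULL

## Newton solve of trigamma(y) = x
.trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Estimate variance-prior hyperparameters by moment matching
#'
#' Fits a scaled inverse chi-square prior to observed sample variances:
#' the mean and spread of \eqn{\log s_g^2} (corrected for the known
#' chi-square contribution at \eqn{d_g} degrees of freedom) identify the
#' prior degrees of freedom \eqn{d_0} and scale \eqn{s_0^2}. When the
#' observed spread does not exceed the chi-square expectation,
#' \eqn{d_0 = \infty} (complete shrinkage).
#'
#' @param s2 Per-protein sample variances.
#' @param df Per-protein residual degrees of freedom (recycled).
#' @return A list with \code{df.prior} and \code{var.prior}.
#' @export
estimateVariancePrior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & df > 0
  s2 <- pmax(s2[ok], 1e-10)
  df <- df[ok]
  if (length(s2) < 2L)
    return(list(df.prior = Inf, var.prior = stats::median(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L)
  evar <- evar - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df.prior = d0, var.prior = s02)
}

#' Moderated one-sample test of protein log2 ratios against zero
#'
#' @param x A numeric matrix of per-protein, per-experiment log2 ratios
#'   (rows = proteins; \code{NA} allowed), or a SummarizedExperiment
#'   carrying a \code{log2ratio} assay.
#' @param alpha Adjusted-p threshold for the enriched flag (default
#'   0.05).
#' @return data.frame with one row per protein: \code{protein},
#'   \code{log2fc} (mean ratio), \code{n} (replicates used), \code{t},
#'   \code{df}, \code{p_value}, \code{adj_p} (Benjamini-Hochberg over
#'   tested proteins), \code{enriched} (adjusted p < \code{alpha}),
#'   \code{tested} (FALSE for proteins with fewer than 2 replicate
#'   ratios, which get \code{NA} statistics). Attributes
#'   \code{"df.prior"} and \code{"var.prior"} record the fitted
#'   hyperparameters.
#' @export
moderatedTest <- function(x, alpha = 0.05) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "log2ratio")
  stopifnot(is.matrix(x))
  n <- rowSums(!is.na(x))
  xbar <- rowMeans(x, na.rm = TRUE)
  s2 <- apply(x, 1L, stats::var, na.rm = TRUE)
  tested <- n >= 2L
  prior <- estimateVariancePrior(s2[tested], n[tested] - 1L)
  d0 <- prior$df.prior
  s02 <- prior$var.prior

  tstat <- rep(NA_real_, length(n))
  dfTot <- rep(NA_real_, length(n))
  pval <- rep(NA_real_, length(n))
  if (any(tested)) {
    dres <- n[tested] - 1L
    s2t <- pmax(s2[tested], 0)
    s2post <- if (is.infinite(d0)) rep(s02, sum(tested))
              else (d0 * s02 + dres * s2t) / (d0 + dres)
    tt <- xbar[tested] / sqrt(s2post / n[tested])
    dd <- d0 + dres
    tstat[tested] <- tt
    dfTot[tested] <- dd
    pval[tested] <- 2 * stats::pt(-abs(tt), df = dd)
  }
  adj <- rep(NA_real_, length(n))
  adj[tested] <- stats::p.adjust(pval[tested], method = "BH")
  out <- data.frame(
    protein = if (!is.null(rownames(x))) rownames(x)
              else as.character(seq_len(nrow(x))),
    log2fc = unname(xbar), n = unname(n), t = unname(tstat),
    df = unname(dfTot), p_value = unname(pval), adj_p = unname(adj),
    enriched = ifelse(is.na(adj), FALSE, adj < alpha),
    tested = unname(tested), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "df.prior") <- d0
  attr(out, "var.prior") <- s02
  out
}

#' Condition-vs-condition differential mode
#'
#' Applies the same moderated machinery to a table of
#' condition-vs-condition log2 ratios (e.g. +stress/-stress), optionally
#' restricted to a prior set of RNA-interacting proteins ("restricted"
#' analysis) or run on all quantified proteins ("extended list").
#'
#' @param se SummarizedExperiment of per-protein condition ratios (assay
#'   \code{log2ratio}), as from \code{\link{aggregateProteinRatios}}.
#' @param restrictTo Optional character vector of protein identifiers;
#'   if supplied it must be non-empty and intersect the rows.
#' @param alpha Adjusted-p threshold.
#' @return \code{\link{moderatedTest}} result for the (restricted) set.
#' @export
differentialMode <- function(se, restrictTo = NULL, alpha = 0.05) {
  if (!is.null(restrictTo)) {
    if (length(restrictTo) == 0L)
      stop("restriction set is empty")
    keep <- rownames(se) %in% restrictTo
    if (!any(keep))
      stop("no quantified protein lies in the restriction set")
    se <- se[keep, ]
  }
  moderatedTest(se, alpha = alpha)
}
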