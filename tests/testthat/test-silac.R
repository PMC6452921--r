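test_that("contaminant and decoy rows are removed, order preserved", {
  tab <- makePeptideTable(h1 = c(100, 200, 300), l1 = c(50, 60, 70))
  tab$contaminant[2] <- TRUE
  out <- filterPeptideRows(tab)
  expect_identical(out$H.E1, c(100, 300))
  ## identity when nothing is flagged
  tab2 <- makePeptideTable(h1 = 1:3 * 10, l1 = 1:3)
  expect_identical(filterPeptideRows(tab2), tab2)
  ## counting oracle on a random table
  set.seed(2)
  tab3 <- makePeptideTable(h1 = runif(50), l1 = runif(50))
  tab3$reverse <- runif(50) < 0.2
  tab3$contaminant <- runif(50) < 0.1
  expect_identical(nrow(filterPeptideRows(tab3)),
                   sum(!(tab3$reverse | tab3$contaminant)))
  expect_error(filterPeptideRows(tab3[, -2]), "protein")
})

test_that("imputation centres draws at the channel q-quantile", {
  design <- silacDesign("E1", "forward")
  ## no missing values: unchanged
  tab <- makePeptideTable(h1 = c(100, 200), l1 = c(50, 60))
  out <- imputeMissing(tab, imputationParams(), design)
  expect_identical(out$H.E1, tab$H.E1)
  expect_false(any(attr(out, "imputed")))

  ## many missing cells in one channel: Monte-Carlo check of the centre
  set.seed(4)
  n <- 12000L
  h <- 2^rnorm(n, 20, 2)
  l <- 2^rnorm(n, 20, 2)
  miss <- seq_len(10000L)
  l[miss] <- NA
  tab <- makePeptideTable(h1 = h, l1 = l)
  params <- imputationParams(q = 0.1, tuneSigma = 0.01, seed = 9)
  out <- imputeMissing(tab, params, design)
  expect_true(all(attr(out, "imputed")[miss, "L.E1"]))
  target <- quantile(log2(l[-miss]), 0.1, names = FALSE)
  sigma <- params$tuneSigma * median(c(sd(log2(h)), sd(log2(l[-miss]))))
  expect_lt(abs(mean(log2(out$L.E1[miss])) - target),
            3 * sigma / sqrt(length(miss)) + 1e-8)
})

test_that("pairs missing in both channels stay missing after imputation", {
  design <- silacDesign(c("E1", "E2"), c("forward", "forward"))
  tab <- makePeptideTable(h1 = c(100, NA, 300), l1 = c(50, NA, 60),
                          h2 = c(NA, 90, 70), l2 = c(11, 80, NA))
  out <- imputeMissing(tab, imputationParams(seed = 2), design)
  ## row 2 missing both channels of E1 -> reset to missing
  expect_true(is.na(out$H.E1[2]) && is.na(out$L.E1[2]))
  ## but observed/imputable elsewhere: E2 of row 2 untouched
  expect_identical(out$H.E2[2], 90)
  ## row 1 missing only H.E2 -> imputed
  expect_false(is.na(out$H.E2[1]))
  expect_true(attr(out, "imputed")[1, "H.E2"])
  expect_error(
    imputeMissing(makePeptideTable(h1 = c(NA, NA), l1 = c(1, 2)),
                  imputationParams(), design["E1"]),
    "no observed values")
})

test_that("ratio orientation always puts the irradiated channel on top", {
  tab <- makePeptideTable(h1 = 100, l1 = 200)
  fwd <- peptideRatios(tab, silacDesign("E1", "forward"))
  expect_identical(fwd$E1, 2)
  rev <- peptideRatios(tab, silacDesign("E1", "reverse"))
  expect_identical(rev$E1, 0.5)
  ## label swap + orientation flip reproduces identical ratios
  swapped <- tab
  swapped$H.E1 <- tab$L.E1
  swapped$L.E1 <- tab$H.E1
  expect_identical(peptideRatios(swapped, silacDesign("E1", "reverse")),
                   fwd)
  ## missing or zero denominators yield NA
  tabz <- makePeptideTable(h1 = c(0, NA), l1 = c(10, 10))
  expect_true(all(is.na(peptideRatios(tabz,
                                      silacDesign("E1", "forward"))$E1)))
})

test_that("protein aggregation takes the median then log2", {
  tab <- makePeptideTable(h1 = c(100, 100, 100), l1 = c(200, 400, 800),
                          proteins = rep("P1", 3))
  pr <- peptideRatios(tab, silacDesign("E1", "forward"))
  se <- aggregateProteinRatios(pr)
  expect_equal(SummarizedExperiment::assay(se, "log2ratio")["P1", "E1"],
               2)
  expect_identical(SummarizedExperiment::assay(se, "npep")["P1", "E1"],
                   3L)
  ## single peptide is its own ratio; order invariance
  pr2 <- pr[c(3, 1, 2), ]
  se2 <- aggregateProteinRatios(pr2)
  expect_equal(SummarizedExperiment::assay(se, "log2ratio"),
               SummarizedExperiment::assay(se2, "log2ratio"))
})

test_that("protein support filter applies the 2-peptides-2-experiments rule", {
  npep <- rbind(A = c(3L, 1L, 0L), B = c(2L, 2L, 0L), C = c(2L, 0L, 2L))
  ratio <- matrix(0, 3, 3, dimnames = dimnames(npep))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = ratio, npep = npep))
  kept <- rownames(filterProteins(se))
  expect_setequal(kept, c("B", "C"))
  ## brute-force counting oracle on random tables
  set.seed(6)
  npepR <- matrix(rpois(300, 1.5), 100, 3,
                  dimnames = list(sprintf("P%03d", 1:100), NULL))
  seR <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = npepR * 0, npep = npepR))
  want <- rownames(npepR)[apply(npepR, 1, function(r)
    sum(r >= 2) >= 2)]
  expect_setequal(rownames(filterProteins(seR)), want)
})

test_that("moderated test matches the reference empirical-Bayes fit", {
  set.seed(12)
  sig <- sqrt(0.3 * 0.2 / rchisq(800, 6))
  X <- matrix(rnorm(3200, 0, rep(sig, 4)), ncol = 4)
  rownames(X) <- sprintf("P%03d", 1:800)
  mine <- moderatedTest(X)
  fit <- limma::eBayes(limma::lmFit(X, matrix(1, 4, 1)))
  expect_equal(attr(mine, "df.prior"), fit$df.prior, tolerance = 1e-10)
  expect_equal(attr(mine, "var.prior"), fit$s2.prior, tolerance = 1e-10)
  expect_equal(mine$t, unname(fit$t[, 1]), tolerance = 1e-12)
  expect_equal(mine$p_value, unname(fit$p.value[, 1]),
               tolerance = 1e-12)
})

test_that("moderated test reduces to the ordinary t-test without shrinkage", {
  set.seed(13)
  X <- matrix(rnorm(30, 1, 0.5), ncol = 3)
  n <- rowSums(!is.na(X))
  s2 <- apply(X, 1, var)
  tOrd <- rowMeans(X) / sqrt(s2 / n)
  ## the formula limit d0 -> 0: posterior variance equals s^2
  d0 <- 0
  s2post <- (d0 * 1 + (n - 1) * s2) / (d0 + n - 1)
  expect_equal(rowMeans(X) / sqrt(s2post / n), tOrd, tolerance = 1e-12)
  ## and the shrunken statistic interpolates between them
  res <- moderatedTest(X)
  expect_true(all(res$tested))
  expect_true(all(is.finite(res$t)))
})

test_that("null simulation keeps the raw type-I error near nominal", {
  set.seed(14)
  nP <- 2000L
  sig <- sqrt(0.35 * 0.15 / rchisq(nP, 5))
  X <- matrix(rnorm(nP * 3, 0, rep(sig, 3)), ncol = 3)
  res <- moderatedTest(X)
  frac <- mean(res$p_value < 0.05)
  ci <- 2.576 * sqrt(0.05 * 0.95 / nP)
  expect_lt(abs(frac - 0.05), ci)
  expect_lte(sum(res$enriched), 2L)
})

test_that("BH-adjusted p-values are monotone in raw p", {
  set.seed(15)
  X <- matrix(rnorm(900, 0, 0.4), ncol = 3)
  res <- moderatedTest(X)
  o <- order(res$p_value)
  expect_true(all(diff(res$adj_p[o]) >= -1e-15))
  expect_true(all(res$adj_p >= res$p_value - 1e-15))
})

test_that("proteins with fewer than two ratios are reported untested", {
  X <- rbind(A = c(1, 2, 1.5), B = c(1, NA, NA), C = c(0.5, 0.7, NA))
  res <- moderatedTest(X)
  expect_false(res$tested[res$protein == "B"])
  expect_true(is.na(res$p_value[res$protein == "B"]))
  expect_false(res$enriched[res$protein == "B"])
  expect_true(all(res$tested[res$protein %in% c("A", "C")]))
})

test_that("end-to-end label swap leaves enrichment results unchanged", {
  sim <- simulateSilacTable(silacSimConfig(nProteins = 250, seed = 8))
  res1 <- silacEnrichment(sim$table, sim$design)
  tab2 <- sim$table
  for (e in names(sim$design)) {
    h <- tab2[[paste0("H.", e)]]
    tab2[[paste0("H.", e)]] <- tab2[[paste0("L.", e)]]
    tab2[[paste0("L.", e)]] <- h
  }
  des2 <- silacDesign(names(sim$design),
                      ifelse(sim$design == "forward", "reverse",
                             "forward"))
  expect_identical(silacEnrichment(tab2, des2), res1)
})

test_that("imputation is deterministic under seed, seeds alter only imputed cells", {
  sim <- simulateSilacTable(silacSimConfig(nProteins = 120, seed = 19))
  tab <- filterPeptideRows(sim$table)
  a <- imputeMissing(tab, imputationParams(seed = 1), sim$design)
  b <- imputeMissing(tab, imputationParams(seed = 1), sim$design)
  expect_identical(a, b)
  c_ <- imputeMissing(tab, imputationParams(seed = 2), sim$design)
  imp <- attr(a, "imputed")
  for (cn in colnames(imp)) {
    expect_identical(a[[cn]][!imp[, cn]], c_[[cn]][!imp[, cn]])
    if (any(imp[, cn]))
      expect_false(identical(a[[cn]][imp[, cn]], c_[[cn]][imp[, cn]]))
  }
})

test_that("differential mode restricts to the prior binder set", {
  X <- matrix(rnorm(60, 0, 0.3), ncol = 3,
              dimnames = list(sprintf("P%02d", 1:20), NULL))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = X, npep = (X * 0) + 3L))
  keep <- sprintf("P%02d", 1:8)
  res <- differentialMode(se, restrictTo = keep)
  expect_true(all(res$protein %in% keep))
  expect_error(differentialMode(se, restrictTo = character(0)),
               "empty")
  expect_error(differentialMode(se, restrictTo = "NOPE"),
               "restriction")
  ## identical conditions: all fold-changes zero
  se0 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = X * 0, npep = (X * 0) + 3L))
  expect_true(all(differentialMode(se0)$log2fc == 0))
})
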