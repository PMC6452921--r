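test_that("crosslink efficiency is site frequency over pool frequency", {
  ## hand-worked single-peptide example
  eff <- crosslinkEfficiency(data.frame(amino_acid = "W"), "AAAW")
  expect_equal(eff$efficiency[eff$amino_acid == "W"], 4)
  expect_equal(eff$efficiency[eff$amino_acid == "A"], 0)
  expect_identical(nrow(eff), 2L)
  ## frequencies each sum to one over observed amino acids
  expect_equal(sum(eff$pool_freq), 1)
  expect_equal(sum(eff$site_freq), 1)
  ## doubling every peptide and site leaves efficiencies unchanged
  sites <- data.frame(amino_acid = c("W", "A"))
  eff1 <- crosslinkEfficiency(sites, c("AAAW", "WKAY"))
  eff2 <- crosslinkEfficiency(rbind(sites, sites),
                              rep(c("AAAW", "WKAY"), 2))
  expect_equal(eff1$efficiency, eff2$efficiency)
  expect_error(crosslinkEfficiency(sites, character(0)), "pool")
})

test_that("uniform site draws give efficiencies near one", {
  set.seed(30)
  peptides <- vapply(1:200, function(i)
    paste(sample(c("A", "K", "W", "S", "F"), 12, replace = TRUE),
          collapse = ""), character(1))
  poolChars <- unlist(strsplit(peptides, ""))
  sites <- data.frame(amino_acid = sample(poolChars, 4000,
                                          replace = TRUE))
  eff <- crosslinkEfficiency(sites, peptides)
  ## Monte-Carlo tolerance: site_freq ~ Binomial(4000, pool_freq)
  tol <- 3 * sqrt(eff$pool_freq * (1 - eff$pool_freq) / 4000) /
    eff$pool_freq
  expect_true(all(abs(eff$efficiency - 1) <= tol))
})

test_that("missed-cleavage fractions count peptides with retained K/R", {
  allZero <- data.frame(missed_cleavages = rep(0L, 4),
                        amino_acid = c("K", "F", "R", "W"))
  mc0 <- missedCleavageStats(allZero)
  expect_identical(mc0$frac_missed, 0)
  expect_identical(mc0$frac_missed_kr, 0)
  ## constructed set: 3 of 4 peptides mc>=1, both K-site peptides mc>=1
  sites <- data.frame(missed_cleavages = c(1L, 2L, 1L, 0L),
                      amino_acid = c("K", "K", "F", "W"))
  mc <- missedCleavageStats(sites)
  expect_equal(mc$frac_missed, 0.75)
  expect_equal(mc$frac_missed_kr, 1)
  expect_identical(mc$n_kr, 2L)
  ## invariant to input order
  mcRev <- missedCleavageStats(sites[4:1, ])
  expect_identical(mc[c("frac_missed", "frac_missed_kr")],
                   mcRev[c("frac_missed", "frac_missed_kr")])
})

test_that("abundance bins split evenly with remainder on top bins", {
  quant <- data.frame(protein = sprintf("P%02d", 1:20),
                      enriched = rep(c(TRUE, FALSE), 10))
  ab <- structure(1:20 * 1.0, names = quant$protein)
  bins <- abundanceBinEnrichment(quant, ab, nBins = 10)
  expect_identical(bins$n, rep(2L, 10))
  expect_true(all(diff(bins$median_abundance) >= 0))
  expect_true(all(bins$ratio >= 0 & bins$ratio <= 1))
  ## all enriched -> every ratio 1
  quant$enriched <- TRUE
  expect_true(all(abundanceBinEnrichment(quant, ab,
                                         nBins = 10)$ratio == 1))
  expect_error(abundanceBinEnrichment(quant[1:5, ], ab, nBins = 10),
               "fewer proteins")
})

test_that("a 30-protein fixture reproduces hand-computed bin ratios", {
  ## abundance 1..30; enriched exactly the multiples of 3
  quant <- data.frame(protein = sprintf("Q%02d", 1:30),
                      enriched = (1:30) %% 3 == 0)
  ab <- structure(as.numeric(1:30), names = quant$protein)
  bins <- abundanceBinEnrichment(quant, ab, nBins = 10)
  ## bins of 3 consecutive abundances each contain exactly one multiple
  expect_identical(bins$n, rep(3L, 10))
  expect_equal(bins$ratio, rep(1 / 3, 10))
  expect_equal(bins$median_abundance, seq(2, 29, by = 3))
  ## exclusion set removed before binning
  bins2 <- abundanceBinEnrichment(quant, ab,
                                  exclude = sprintf("Q%02d", 1:10),
                                  nBins = 10)
  expect_identical(sum(bins2$n), 20L)
})

test_that("colocalization flags planted proximity and respects the window", {
  set.seed(33)
  nP <- 50
  lens <- sample(300:600, nP, replace = TRUE)
  ids <- sprintf("P%02d", 1:nP)
  phos <- lapply(lens, function(L) sort(sample.int(L, 3)))
  names(phos) <- ids
  ## planted: crosslinks exactly at phosphosites
  sites <- do.call(rbind, lapply(1:nP, function(i)
    data.frame(protein = ids[i], position = phos[[i]])))
  lenv <- structure(lens, names = ids)
  res <- phosphositeColocalization(sites, phos, lenv,
                                   colocalizationParams(seed = 2))
  expect_identical(unname(res$observed["inside"]), nrow(sites))
  expect_lt(res$p_value, 1e-10)
  expect_equal(sum(res$expected), nrow(sites))
  ## window 0 with no exact overlap -> inside count 0
  off <- sites
  off$position <- pmin(off$position + 1L, rep(lens, each = 3))
  res0 <- phosphositeColocalization(
    off[off$position != sites$position, ], phos, lenv,
    colocalizationParams(window = 0, seed = 2))
  expect_identical(unname(res0$observed["inside"]), 0L)
  expect_error(phosphositeColocalization(sites, list(), lenv),
               "no phosphosites")
})

test_that("colocalization is deterministic under seed", {
  set.seed(34)
  ids <- sprintf("P%d", 1:10)
  lens <- structure(sample(200:400, 10), names = ids)
  phos <- lapply(lens, function(L) sort(sample.int(L, 2)))
  names(phos) <- ids
  sites <- data.frame(protein = rep(ids, 2),
                      position = c(vapply(lens, function(L)
                        sample.int(L, 1), integer(1)),
                        vapply(lens, function(L)
                          sample.int(L, 1), integer(1))))
  a <- phosphositeColocalization(sites, phos, lens,
                                 colocalizationParams(seed = 7))
  b <- phosphositeColocalization(sites, phos, lens,
                                 colocalizationParams(seed = 7))
  expect_identical(a, b)
  d <- phosphositeColocalization(sites, phos, lens,
                                 colocalizationParams(seed = 8))
  expect_false(identical(a$expected, d$expected))
})

test_that("proteins without phosphosites only feed the outside count", {
  lens <- c(A = 100L, B = 100L)
  phos <- list(A = 50L)
  sites <- data.frame(protein = c("A", "B"), position = c(50L, 50L))
  res <- phosphositeColocalization(sites, phos, lens,
                                   colocalizationParams(seed = 1))
  expect_identical(unname(res$observed["inside"]), 1L)
  expect_identical(unname(res$observed["outside"]), 1L)
})
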