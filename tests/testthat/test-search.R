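test_that("candidate index is equivalent to a brute-force scan", {
  pep <- data.frame(sequence = "TAYIAK", protein = "P1", start = 3L,
                    missed_cleavages = 0L, is_decoy = FALSE,
                    n_ox = 0L, ox_positions = "",
                    mass = peptideMass("TAYIAK"))
  adducts <- enumerateTargetedAdducts(maxLen = 1, alphabet = "4tU")
  idx <- buildCandidateIndex(pep, adducts)
  expect_identical(length(idx@mass), 6L)
  hit <- queryCandidates(idx, pep$mass + adducts$precursor_mass_da[3],
                         6)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$adductRow, 3L)

  ## 1,000 random candidates vs linear scan
  set.seed(5)
  pepN <- pep[rep(1, 250), ]
  pepN$mass <- runif(250, 600, 4000)
  idxN <- buildCandidateIndex(pepN, adducts[1:4, ])
  allMass <- rep(pepN$mass, times = 4) +
    rep(adducts$precursor_mass_da[1:4], each = 250)
  for (q in runif(25, 900, 4300)) {
    got <- queryCandidates(idxN, q, 50)
    want <- which(abs(allMass - q) <= q * 50e-6)
    expect_identical(sort(got$mass),
                     sort(allMass[want]))
  }
})

test_that("fragment generation covers b/y series with stub logic", {
  cfg <- xlSearchConfig()
  seqs <- c("TAYIAK", "SAMPLER", "WEAKNESS")
  for (s in seqs) {
    n <- nchar(s)
    for (site in c(1L, n)) {
      fr <- theoreticalFragments(s, 340.013027, site, cfg, 2L)
      ## backbone count before stub/loss/charge expansion
      expect_identical(nrow(unique(fr[, c("series", "index")])),
                       2L * (n - 1L))
      ## positional oracle: a fragment may carry a stub iff its residue
      ## range contains the site
      spans <- ifelse(fr$series == "b", site <= fr$index,
                      site > n - fr$index)
      expect_true(all(fr$stub[!spans] == 0))
      expect_true(all(tapply(fr$stub, paste(fr$series, fr$index),
                             max)[unique(paste(fr$series, fr$index)[spans])] > 0))
    }
  }
  ## site = 1: only b ions can carry stubs
  fr <- theoreticalFragments("TAYIAK", 340.013027, 1L, cfg, 2L)
  expect_true(all(fr$series[fr$stub > 0] == "b"))
  ## site = n: only y ions can carry stubs
  fr <- theoreticalFragments("TAYIAK", 340.013027, 6L, cfg, 2L)
  expect_true(all(fr$series[fr$stub > 0] == "y"))
  expect_error(theoreticalFragments("TAYIAK", 340, 7L), "invalid")
})

test_that("fragment m/z reproduces a hand calculation", {
  r <- residueMasses()
  fr <- theoreticalFragments("AKY", 340.013027, 3L, xlSearchConfig(),
                             2L)
  b2 <- fr[fr$series == "b" & fr$index == 2L & fr$charge == 1L &
             fr$stub == 0 & fr$loss == "none", ]
  expect_equal(b2$mz, r[["A"]] + r[["K"]] + protonMass(),
               tolerance = 1e-10)
  y1 <- fr[fr$series == "y" & fr$index == 1L & fr$charge == 1L &
             fr$stub == 340.013027 & fr$loss == "none", ]
  expect_equal(y1$mz, r[["Y"]] + monoisotopicMass("H2O") +
                 340.013027 + protonMass(), tolerance = 1e-9)
})

test_that("a complete noiseless spectrum scores full coverage", {
  fr <- theoreticalFragments("TAYIAGLK", 340.013027, 4L,
                             xlSearchConfig(), 2L)
  sp <- Spectrum("full", 600, 2L, unique(fr$mz))
  st <- scorePsm(sp, fr)
  expect_identical(st$coverage, 1)
  expect_identical(st$matched, length(unique(fr$mz)))
  expect_gt(st$score, 10)
  ## empty spectrum
  empty <- Spectrum("none", 600, 2L, numeric(0))
  st0 <- scorePsm(empty, fr)
  expect_identical(st0[c("score", "coverage")],
                   list(score = 0, coverage = 0))
})

test_that("random-spectrum match counts agree with the binomial model", {
  cfg <- xlSearchConfig(allowOneDa = FALSE)
  fr <- theoreticalFragments("TAYIAGLKWS", 340.013027, 5L, cfg, 2L)
  N <- nrow(fr)
  set.seed(99)
  ks <- replicate(200, {
    sp <- Spectrum("rand", 600, 2L, runif(150, 100, 1500))
    scorePsm(sp, fr, cfg)$matched
  })
  tol <- cfg@ms2TolPpm * 1e-6
  p <- 150 * 2 * tol * mean(fr$mz) / 1400
  expect_lt(abs(mean(ks) - N * p),
            3 * sqrt(N * p * (1 - p) / 200) + 0.5)
})

test_that("adding a matched peak never decreases the score", {
  cfg <- xlSearchConfig()
  fr <- theoreticalFragments("TAYIAGLK", 340.013027, 4L, cfg, 2L)
  set.seed(7)
  for (i in 1:10) {
    baseMz <- c(sample(fr$mz, 8), runif(40, 100, 1500))
    sp1 <- Spectrum("a", 600, 2L, baseMz)
    unmatched <- setdiff(fr$mz, baseMz)
    sp2 <- Spectrum("b", 600, 2L, c(baseMz, sample(unmatched, 1)))
    expect_gte(scorePsm(sp2, fr, cfg)$score,
               scorePsm(sp1, fr, cfg)$score)
  }
})

test_that("planted noiseless spectra are identified with exact site", {
  fx <- makeIndex(nProteins = 12L, seed = 31L)
  tpep <- fx$peptides[!fx$peptides$is_decoy &
                        nchar(fx$peptides$sequence) <= 18, ]
  set.seed(13)
  for (i in 1:10) {
    pi <- sample(nrow(tpep), 1)
    ai <- sample(nrow(fx$adducts), 1)
    site <- sample(nchar(tpep$sequence[pi]), 1)
    sim <- simulateConjugateSpectrum(
      tpep$sequence[pi], fx$adducts$precursor_mass_da[ai], site,
      spectrumSimConfig(charge = 3L, seed = 500 + i), id = "pl")
    best <- searchSpectrum(sim$spectrum, fx$index)$best
    expect_identical(best$sequence, tpep$sequence[pi])
    expect_identical(best$site, site)
    expect_equal(best$adduct_mass, fx$adducts$precursor_mass_da[ai],
                 tolerance = 1e-9)
    expect_false(best$is_decoy)
  }
})

test_that("spectra far from any candidate return an empty result", {
  fx <- makeIndex(nProteins = 3L, seed = 37L)
  ## precursor 50 ppm away from the nearest candidate
  m <- fx$index@mass[100]
  sp <- Spectrum("off", (m * (1 + 50e-6) + 2 * protonMass()) / 2, 2L,
                 c(300, 400))
  expect_identical(nrow(searchSpectrum(sp, fx$index)$best), 0L)
  ## out-of-range charge is skipped
  spz <- Spectrum("z1", (m + protonMass()) / 1, 1L, c(300, 400))
  res <- searchSpectrum(spz, fx$index)
  expect_identical(nrow(res$best), 0L)
})

test_that("spectra without stub ions yield an undefined site", {
  fx <- makeIndex(nProteins = 5L, seed = 41L)
  tpep <- fx$peptides[!fx$peptides$is_decoy &
                        nchar(fx$peptides$sequence) <= 15, ]
  pep <- tpep[which.max(nchar(tpep$sequence)), ]
  amass <- fx$adducts$precursor_mass_da[2]
  fr <- theoreticalFragments(pep$sequence, amass, 2L, xlSearchConfig(),
                             2L)
  noStub <- fr[fr$stub == 0, ]
  sp <- Spectrum("nostub",
                 (pep$mass + amass + 2 * protonMass()) / 2, 2L,
                 unique(noStub$mz))
  best <- searchSpectrum(sp, fx$index)$best
  expect_identical(nrow(best), 1L)
  expect_true(is.na(best$site))
})

test_that("search results are byte-identical across reruns", {
  fx <- makeIndex(nProteins = 6L, seed = 43L)
  tpep <- fx$peptides[!fx$peptides$is_decoy, ]
  sims <- lapply(1:5, function(i)
    simulateConjugateSpectrum(
      tpep$sequence[i * 3], fx$adducts$precursor_mass_da[1], 1L,
      spectrumSimConfig(detectionProb = 0.7, nNoise = 25L, ppmSd = 5,
                        charge = 2L, seed = i),
      id = paste0("s", i))$spectrum)
  r1 <- searchSpectra(sims, fx$index)
  r2 <- searchSpectra(sims, fx$index)
  expect_identical(r1, r2)
})
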