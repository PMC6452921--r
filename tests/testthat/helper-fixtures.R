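## Shared fixtures, built in code at test time.

## printed 4tU-derived retained-fragment masses (label -> Da)
printedStubMasses <- function() {
  c("4tU base" = 128.004435,
    "4tU base-H2S" = 94.016713,
    "4tUMP-HPO3-H2S" = 226.058971,
    "4tUMP-H2S" = 306.025302,
    "4tUMP" = 340.013027,
    "4tUMP-HPO3" = 260.046696,
    "4tUMP+HPO3-H2S" = 385.991636,
    "4tUMP+HPO3" = 419.979358)
}

## small target+decoy candidate index over a synthetic proteome
makeIndex <- function(nProteins = 15L, seed = 11L, maxLenAdduct = 1L,
                      alphabet = "4tU", allowMetOxidation = FALSE) {
  prot <- generateProteome(nProteins, seed = seed)
  all <- rbind(prot, generateDecoys(prot))
  pep <- applyModifications(digestDatabase(all),
                            allowMetOxidation = allowMetOxidation)
  adducts <- enumerateTargetedAdducts(maxLen = maxLenAdduct,
                                      alphabet = alphabet)
  list(proteins = prot, peptides = pep, adducts = adducts,
       index = buildCandidateIndex(pep, adducts))
}

## peptide evidence table with explicit intensities (NA = missing)
makePeptideTable <- function(h1, l1, h2 = NULL, l2 = NULL,
                             proteins = NULL) {
  n <- length(h1)
  tab <- data.frame(
    sequence = sprintf("PEPTIDE%dK", seq_len(n)),
    protein = if (is.null(proteins)) sprintf("P%02d", seq_len(n))
              else proteins,
    reverse = FALSE, contaminant = FALSE,
    H.E1 = h1, L.E1 = l1, stringsAsFactors = FALSE)
  if (!is.null(h2)) {
    tab$H.E2 <- h2
    tab$L.E2 <- l2
  }
  tab
}
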