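---
title: "Methods: targeted RNA-peptide crosslink search and UV-enrichment quantification"
author: "trappkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted RNA-peptide crosslink search and UV-enrichment quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trappkit)
```

## Scope

UV crosslinking covalently traps direct RNA-protein contacts. Two
computational problems arise downstream. First, in SILAC-based
enrichment experiments (irradiated versus non-irradiated cultures mixed
per replicate), which proteins are reproducibly enriched by UV -- i.e.
which proteins are RNA-binders? Second, in experiments where the bound
RNA is nuclease-digested to mono/oligonucleotides and the conjugated
peptides are sequenced by tandem MS, which spectrum belongs to which
peptide, carrying which RNA adduct, crosslinked at which residue?

`trappkit` implements both pipelines on top of exact monoisotopic mass
arithmetic, together with post-identification site statistics and
seeded synthetic-data generators that give every stage a
ground-truthed input.

## Adduct chemistry

Experiments use 4-thiouridine (4tU), a photoactivatable uridine
analogue incorporated metabolically and crosslinked at ~350 nm.
Nuclease P1 digestion leaves 5'-monophosphate nucleotides, so the
peptide-bound RNA remnant is modelled as a multiset of 1-3 nucleoside
monophosphates, at least one of them 4tU (the crosslinking residue),
condensed by phosphodiester bonds (one water lost per bond), in one of
six neutral states: unmodified, -H2S, -HPO3, -HPO3-H2S, +HPO3 and
+HPO3-H2S. H2S loss is the hallmark of 4tU crosslink chemistry; the
phosphate gain/loss states absorb incomplete digestion and in-source
chemistry.

During collision-induced dissociation the nucleotide is cleavable:
fragment ions that span the crosslinked residue may retain either
nothing, the full adduct, or one of eight 4tU-derived stub masses
(the 4-thiouracil base with and without H2S, and 4tU monophosphate in
six neutral states). Every one of these masses is recomputed at run
time from molecular formulas over a single table of NIST monoisotopic
atomic masses:

```{r}
retentionFragmentSet()
```

The 419.979358 Da entry is sometimes labelled "uridine monophosphate
+ HPO3" in protocol descriptions of this chemistry; its value equals
4-thiouridine monophosphate + HPO3, and it is treated as such here --
that reading keeps the arithmetic consistent with the remaining seven
entries.

Golden-mass tests use a tolerance of 2e-5 Da, absorbing drift between
atomic-mass table editions (the observed agreement is below 5e-6 Da).

## Digestion and decoys

Trypsin cleavage is modelled C-terminal to K/R including before
proline (the trypsin\\P convention used by the targeted search
set-up); classical specificity is a flag. Defaults: up to 2 missed
cleavages, minimum length 6. The fixed cysteine modification defaults
to carbamidomethyl (+57.021464 Da) since samples are alkylated with
iodoacetamide; carboxymethyl is selectable. Methionine oxidation is
variable, one candidate per oxidized subset up to a cap of 2.

Decoys are one per target, reversed by default; a shuffle mode
permutes residues within tryptic segments keeping terminal K/R so the
decoy peptide mass distribution stays realistic. Targets and decoys
are searched together (decoy competition).

## Spectrum search and scoring

Candidates are (peptide, adduct) pairs indexed by neutral precursor
mass; a spectrum of charge z queries the index at
`z * mz - z * protonMass()` with a 6 ppm window. For each candidate,
every residue position is scored as the crosslink site: fragments
spanning the site are generated once per stub mass, fragments outside
it bare, with at most one neutral loss (H2O/NH3) per fragment and
fragment charges up to 2 (ion-trap MS2 convention). Matching uses a
20 ppm window, optionally extended by +/-1.00335/z Th channels to
capture 1-Da assignment errors.

There is no standard score for cleavable-adduct matches of this kind,
so the package defines its own: matched peaks are
counted (each peak creditable once) and the score is the -log10
binomial survival probability of at least that many matches among the
N theoretical fragments, with the per-fragment match probability
estimated from the spectrum's peak density times the tolerance window.
This score is parameter-light, monotone in evidence, and calibratable
by simulation; it is not a reimplementation of any published engine.

**Site localization.** A site is reported only when it is determined
by the data: the best site must strictly out-score the runner-up
*and* be supported by at least one matched stub-bearing ion that is
(i) matched in the exact mass window (the 1-Da-off channels are
excluded), (ii) free of neutral losses, and (iii) spans the best site
but not the runner-up. Otherwise the site is "undefined"; undefined
PSMs survive FDR but are dropped before site-level deduplication.
Restricting the localization evidence to loss-free exact matches was
a deliberate choice: in peak-dense spectra, loss-bearing or 1-Da-off
stub assignments coincide with backbone ions often enough to fake
localization evidence.

**FDR.** PSMs are sorted by descending score (decoys first at ties --
conservative); running FDR is decoys/targets; q-values are the
cumulative minimum from the bottom; the accepted set is the largest
prefix with q at or below the threshold (default 1%). The plain
decoy/target ratio carries no +1 correction; it is accurate for
analyses of realistic size and is
applied to one pooled PSM list per analysis, never to tiny batches,
where the discrete first-decoy effect would make it anti-conservative.

**Deduplication.** Accepted target PSMs with defined sites are
collapsed first by (protein, absolute residue), then by (peptide,
adduct), keeping the best score at each step, yielding unique
crosslink sites.

## SILAC UV-enrichment quantification

Rows flagged as decoy or contaminant are removed. Missing intensities
are left-censored (low-abundance signals drop below detection), so
they are imputed MinProb-style: per channel (experiment x label),
missing values are drawn from a Gaussian centred at the q-quantile
(default 0.1) of the channel's observed log2-intensity distribution
with standard deviation `tuneSigma` times the median of per-channel
observed sds. `tuneSigma` defaults to 0.01; the preset for yeast
UVC-crosslinking data is 0.0035 (tighter draws). MinProb
implementations differ in their internal scaling, so the definition
above is normative for this package, with the usual q and tune-sigma
semantics (smaller tune-sigma, tighter left-censored draws). Where a
peptide is missing in both channels of an experiment the imputed pair
is removed again -- it carries no ratio information; pairs with
exactly one observed channel keep their imputed partner, which is what
lets "superenriched" peptides (present only with UV) drive the
recovery of strong binders.

Random draws are keyed by (row, experiment, channel role), where the
role -- irradiated or control -- is given by the experiment's
orientation. This makes the whole pipeline exactly invariant under
swapping every SILAC label and flipping the orientations, a property
the test suite asserts byte-for-byte.

Ratios put the irradiated channel in the numerator (light/heavy in
forward experiments, heavy/light in reverse). Protein ratios are the
median over peptides, taken on the ratio scale and then
log2-transformed (the order matters only for even peptide counts and
is fixed as a package convention), using the leading razor
protein as identifier. Proteins need >= 2 peptides in >= 2 experiments.

Significance uses a one-sample empirical-Bayes moderated t-test of
log2 ratios against zero: the posterior variance is
(d0 s0^2 + d s^2)/(d0 + d), the statistic has d0 + d degrees of
freedom, and (d0, s0^2) are estimated by moment matching on log
sample variances. The implementation is self-contained; the test
suite verifies exact numerical agreement (t, p, d0, s0^2) with the
reference empirical-Bayes implementation on shared fixtures.
Benjamini-Hochberg adjustment at 0.05 flags enriched proteins.

The differential (stress) mode applies the same machinery to
condition-vs-condition ratio tables, optionally restricted to a prior
RNA-interacting set.

## Site statistics

*Crosslink efficiency* of an amino acid is its frequency among
crosslinked residues divided by its frequency in all crosslinked
peptides; amino acids absent from the pool are omitted rather than
divided by zero. *Missed-cleavage statistics* report the fraction of
crosslinked peptides retaining 1-2 missed cleavages, overall and for
K/R crosslink sites. *Abundance-binned enrichment* sorts detected
proteins by abundance into 10 equal-count bins (remainder spread over
the top bins) and reports per-bin median abundance and the enriched
fraction.

*Phosphosite colocalization* counts crosslink sites within 20
residues of a phosphosite on the same protein ("inside") versus
outside; expected counts come from 100 seeded shuffles that redraw
each protein's phosphosites uniformly without replacement (per-protein
counts preserved) with a seeded generator; a chi-square
goodness-of-fit over the two categories (1 df, no continuity
correction, expected = averaged shuffled counts) gives the p-value.
Shuffled phosphosites may land on any residue by default; an
S/T/Y-restricted mode is available (`styOnly`) for the stricter
reading that phosphosites only occupy phosphorylatable residues.
Proteins without phosphosites contribute only
to the outside count; an expected count of zero in either category is
an error suggesting more shuffles.

## Synthetic data: what it emulates, what it does not

`generateProteome()` draws sequences with a combined K/R frequency of
0.11 (tryptic peptides of realistic length). `simulateConjugateSpectrum()`
samples theoretical fragments at a detection probability, perturbs
masses with Gaussian ppm error, and adds uniform noise peaks;
intensities are exponential (cosmetic -- the default score ignores
intensity). `simulateSilacTable()` plants a configurable fraction of
binders (default 10%) with a log2 effect of 2 in the irradiated
channel, log-normal peptide intensities (log10 mean 7, sd 0.8),
per-cell multiplicative noise of 0.35 log2 units (about 27% CV per
channel, a deliberately conservative choice relative to typical SILAC
precision), and logistic missing-not-at-random censoring
(midpoint log10 = 6, slope 2, i.e. roughly 10-20% missing cells,
preferentially dim ones) -- a smooth, controllable stand-in for the
hard detection limit of a real instrument. Three experiments with one
label swap are the default design.

The generators do **not** model isotope envelopes, chromatography,
co-isolation, peptide-level identification error in the SILAC tables,
shared peptides, or correlated (batch) noise. Passing the test suite
therefore demonstrates correctness of the statistical machinery under
the stated generative model, not end-to-end performance on raw
instrument data.

## Problem sizes and empirical checks

The test suite verifies, at these scales (chosen to make the checks
sharp while keeping the suite quick):

- 200 noiseless planted spectra over a 100-protein proteome:
  rank-1 recovery of (peptide, adduct, site) at or above 99%.
- 20 seeded batches of 50 planted (60% fragment detection, 4 ppm
  error, 40 noise peaks) plus 50 pure-noise spectra over 25-protein
  proteomes, pooled into one FDR analysis: realized false discovery
  proportion at most 2% at the 1% threshold.
- A 5,000-protein null (protein-specific variances, 3 replicates):
  raw p < 0.05 fraction inside the binomial 99% CI of 0.05, and BH
  calls near zero.
- Planted 4-fold binders at 10% prevalence, 3 seeds of 1,000
  proteins: sensitivity at least 90% with realized FDR at most 10%.
- 500 null colocalization datasets (20 proteins each): type-I rate
  inside the binomial 99% CI of 0.05; 20 planted datasets: p < 0.05
  in at least 95%.

`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed. Results at the scale of full experimental
datasets (thousands of quantified proteins, hundreds of crosslink
sites) require deposited instrument data and are outside these
desk-scale checks.

## Numerical and design notes

- All positions are 1-based inclusive in user-facing tables.
- Precursor neutral mass is z(m/z) - z x proton; no isotope-error
  correction by default.
- Median of an even number of peptide ratios is the midpoint mean,
  taken on the ratio scale before log2.
- Sample variances of exactly zero are floored at 1e-10 before the
  variance-prior fit.
- Ties in the FDR sort rank decoys first; all outputs are
  deterministic given inputs and seeds (byte-identical reruns).
- The candidate index stores all (peptide, adduct) masses as one
  sorted vector; queries are binary searches, verified against a
  linear-scan oracle.

## Known limitations

- The match score is this package's own; absolute score values are
  not comparable to any published engine.
- Hydrogen losses at the crosslink bond (reported for lysine sites)
  are not modelled.
- Protein inference is leading-protein assignment only; I/L are not
  disambiguated.
- MGF and FASTA are the only ingestion formats (no mzML/raw).
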