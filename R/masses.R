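#' @title Monoisotopic mass arithmetic for peptides and RNA adducts
#'
#' @description
#' The targeted crosslink search identifies peptides carrying small RNA
#' adducts derived from 4-thiouridine (4tU), the photoactivatable uridine
#' analogue used in metabolic-labelling UV-crosslinking experiments.
#' Every mass the package uses -- amino-acid residues, nucleotides, adduct
#' precursor deltas and the cleavable "stub" masses retained on fragment
#' ions -- is derived at run time from a single table of elemental
#' monoisotopic masses, so the chemistry is a computed artifact rather
#' than a list of literals.
#'
#' @name chem-masses
NULL

## NIST/CODATA monoisotopic atomic masses (Da), >= 9 decimals where known.
.ELEMENT_MASSES <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

## Mass of a proton (charge carrier), Da.
.PROTON_MASS <- 1.007276466879

#' Elemental monoisotopic mass table
#'
#' @return Named numeric vector mapping element symbols to monoisotopic
#'   masses in Da. Contains at least H, C, N, O, P and S.
#' @examples
#' elementMassTable()[["S"]]
#' @export
elementMassTable <- function() .ELEMENT_MASSES

#' Mass of a proton in Da
#' @return Numeric scalar.
#' @export
protonMass <- function() .PROTON_MASS

#' Parse a molecular formula string
#'
#' Formulas use Hill-style element counts, e.g. \code{"C4H4N2OS"}.
#' Counts accumulate if an element appears twice.
#'
#' @param x Character scalar formula, or an already-parsed named integer
#'   vector (returned unchanged after validation).
#' @return Named integer vector of element counts (all counts >= 0).
#' @examples
#' molecularFormula("H2O")
#' @export
molecularFormula <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("numeric formula must be a named vector of element counts")
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    if (!nzchar(x)) return(structure(integer(0), names = character(0)))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(x))
      stop("cannot parse molecular formula: ", x)
    elems <- sub("[0-9]*$", "", toks)
    nums <- sub("^[A-Za-z]+", "", toks)
    counts <- ifelse(nzchar(nums), as.integer(nums), 1L)
    names(counts) <- elems
    counts <- tapply(counts, names(counts), sum)
    counts <- structure(as.integer(counts), names = names(counts))
  }
  if (any(counts < 0)) stop("negative element count in formula")
  counts[counts > 0L]
}

#' Combine molecular formulas
#'
#' Element-wise addition/subtraction of element-count vectors.
#' Subtraction that would produce a negative count is an error: the
#' result would not be a molecule.
#'
#' @param a,b Formulas (strings or named integer vectors).
#' @return Named integer vector.
#' @export
addFormulas <- function(a, b) {
  a <- molecularFormula(a); b <- molecularFormula(b)
  elems <- union(names(a), names(b))
  out <- structure(integer(length(elems)), names = elems)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out > 0L]
}

#' @rdname addFormulas
#' @export
subtractFormulas <- function(a, b) {
  a <- molecularFormula(a); b <- molecularFormula(b)
  elems <- union(names(a), names(b))
  out <- structure(integer(length(elems)), names = elems)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0L))
    stop("formula subtraction yields negative count for: ",
         paste(names(out)[out < 0L], collapse = ", "))
  out[out > 0L]
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string or named integer count vector.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopicMass("C4H4N2OS")  # 4-thiouracil base fragment
#' @export
monoisotopicMass <- function(formula) {
  f <- molecularFormula(formula)
  if (length(f) == 0L) return(0)
  unknown <- setdiff(names(f), names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(.ELEMENT_MASSES[names(f)] * f)
}

## ---------------------------------------------------------------------------
## Nucleotide chemistry
## ---------------------------------------------------------------------------

## Free nucleoside 5'-monophosphates (as released by nuclease P1) and the
## nucleobase fragment of each base. 4tU is uridine with one ring oxygen
## replaced by sulfur.
.NUCLEOTIDE_SPECS <- list(
  A     = list(nmp = "C10H14N5O7P", base = "C5H5N5"),
  C     = list(nmp = "C9H14N3O8P",  base = "C4H5N3O"),
  G     = list(nmp = "C10H14N5O8P", base = "C5H5N5O"),
  U     = list(nmp = "C9H13N2O9P",  base = "C4H4N2O2"),
  `4tU` = list(nmp = "C9H13N2O8PS", base = "C4H4N2OS")
)

#' Nucleotide formula specifications
#'
#' Free nucleoside 5'-monophosphate and nucleobase-fragment formulas for
#' A, C, G, U and 4-thiouridine (\code{"4tU"}).
#'
#' @param base Optional base code; if missing, the full list is returned.
#' @return A list with elements \code{nmp} and \code{base} (formula
#'   strings), or the named list of all specs.
#' @export
nucleotideSpec <- function(base) {
  if (missing(base)) return(.NUCLEOTIDE_SPECS)
  if (!base %in% names(.NUCLEOTIDE_SPECS))
    stop("unknown base code: ", base)
  .NUCLEOTIDE_SPECS[[base]]
}

## Neutral modification deltas applied to whole adducts. Signs encode
## gain (+) or loss (-) of the group; masses derived from formulas.
.NEUTRAL_MODIFICATIONS <- list(
  "none"       = list(),
  "-H2S"       = list(list(sign = -1, formula = "H2S")),
  "-HPO3"      = list(list(sign = -1, formula = "HPO3")),
  "-HPO3-H2S"  = list(list(sign = -1, formula = "HPO3"),
                      list(sign = -1, formula = "H2S")),
  "+HPO3"      = list(list(sign = +1, formula = "HPO3")),
  "+HPO3-H2S"  = list(list(sign = +1, formula = "HPO3"),
                      list(sign = -1, formula = "H2S"))
)

#' Neutral modification states for RNA adducts
#'
#' The six whole-adduct neutral states considered by the targeted
#' search: unmodified, loss of H2S (the hallmark of 4tU crosslink
#' chemistry), loss/gain of HPO3 (phosphate), and their combinations.
#'
#' @return Character vector of modification labels.
#' @export
neutralModifications <- function() names(.NEUTRAL_MODIFICATIONS)

.modificationDelta <- function(modification) {
  if (!modification %in% names(.NEUTRAL_MODIFICATIONS))
    stop("unknown neutral modification: ", modification)
  parts <- .NEUTRAL_MODIFICATIONS[[modification]]
  if (length(parts) == 0L) return(0)
  sum(vapply(parts, function(p) p$sign * monoisotopicMass(p$formula),
             numeric(1)))
}

## ---------------------------------------------------------------------------
## Retained (stub) fragment masses
## ---------------------------------------------------------------------------

#' Cleavable stub masses retained on peptide fragment ions
#'
#' During collision-induced dissociation the crosslinked nucleotide
#' cleaves, leaving a characteristic portion of 4tU attached to the
#' peptide fragment. The default set holds the eight 4tU-derived
#' retained masses used by the targeted search: the 4-thiouracil base
#' (with and without H2S loss) and 4-thiouridine monophosphate in six
#' neutral states. All masses are recomputed from molecular formulas.
#'
#' @return A data.frame with columns \code{label} and \code{mass} (Da),
#'   8 rows.
#' @examples
#' retentionFragmentSet()
#' @export
retentionFragmentSet <- function() {
  base4tU <- .NUCLEOTIDE_SPECS[["4tU"]]$base
  nmp4tU <- .NUCLEOTIDE_SPECS[["4tU"]]$nmp
  mBase <- monoisotopicMass(base4tU)
  mNmp <- monoisotopicMass(nmp4tU)
  labels <- c("4tU base", "4tU base-H2S",
              "4tUMP-HPO3-H2S", "4tUMP-H2S", "4tUMP", "4tUMP-HPO3",
              "4tUMP+HPO3-H2S", "4tUMP+HPO3")
  masses <- c(
    mBase,
    mBase + .modificationDelta("-H2S"),
    mNmp + .modificationDelta("-HPO3-H2S"),
    mNmp + .modificationDelta("-H2S"),
    mNmp,
    mNmp + .modificationDelta("-HPO3"),
    mNmp + .modificationDelta("+HPO3-H2S"),
    mNmp + .modificationDelta("+HPO3")
  )
  data.frame(label = labels, mass = masses)
}

## ---------------------------------------------------------------------------
## RnaAdduct
## ---------------------------------------------------------------------------

.adductLabel <- function(composition, modification) {
  comp <- paste(sort(composition), collapse = "+")
  if (identical(modification, "none")) comp
  else paste0(comp, " ", modification)
}

.adductMass <- function(composition, modification) {
  nmp <- vapply(composition,
                function(b) monoisotopicMass(nucleotideSpec(b)$nmp),
                numeric(1))
  n <- length(composition)
  ## phosphodiester condensation: an n-mer loses (n-1) waters
  sum(nmp) - (n - 1L) * monoisotopicMass("H2O") +
    .modificationDelta(modification)
}

#' Construct an RNA adduct
#'
#' An \code{RnaAdduct} is a 1--3 nucleotide RNA modification attached to
#' a peptide, at least one residue of which is 4-thiouridine (the
#' crosslinking residue). Its precursor mass is the sum of nucleoside
#' 5'-monophosphate masses minus one water per phosphodiester bond,
#' plus the neutral modification delta.
#'
#' @param composition Character vector of base codes (length 1--3,
#'   containing at least one \code{"4tU"}).
#' @param modification One of \code{neutralModifications()}.
#' @return An \linkS4class{RnaAdduct} object.
#' @examples
#' rnaAdduct("4tU", "+HPO3-H2S")
#' @export
rnaAdduct <- function(composition, modification = "none") {
  new("RnaAdduct",
      composition = as.character(composition),
      modification = modification,
      label = .adductLabel(composition, modification),
      precursorMass = .adductMass(composition, modification))
}

#' Precursor mass delta of an RNA adduct
#'
#' @param adduct An \linkS4class{RnaAdduct}.
#' @return Mass in Da added to the peptide precursor.
#' @export
adductPrecursorMass <- function(adduct) {
  stopifnot(is(adduct, "RnaAdduct"))
  adduct@precursorMass
}

## all multisets of size k over alphabet, as a character matrix (k rows)
.multisets <- function(alphabet, k) {
  idx <- seq_along(alphabet)
  combs <- utils::combn(length(alphabet) + k - 1L, k)
  ## stars-and-bars bijection: subtract 0:(k-1) to get non-decreasing tuples
  tuples <- combs - (seq_len(k) - 1L)
  matrix(alphabet[tuples], nrow = k)
}

#' Enumerate the targeted adduct search space
#'
#' All RNA adducts of up to \code{maxLen} nucleotides over the given
#' alphabet that contain at least one 4tU residue, crossed with the
#' neutral modification set.
#'
#' @param maxLen Maximum number of nucleotides (default 3).
#' @param alphabet Base codes to draw from (must contain \code{"4tU"}).
#' @param modifications Character vector of neutral modification labels.
#' @return A data.frame with columns \code{label}, \code{composition}
#'   (\code{"+"}-joined base codes), \code{modification} and
#'   \code{precursor_mass_da}, one row per (composition, modification)
#'   pair, sorted by mass.
#' @examples
#' nrow(enumerateTargetedAdducts(maxLen = 1, alphabet = "4tU"))  # 6
#' @export
enumerateTargetedAdducts <- function(maxLen = 3L,
                                     alphabet = c("A", "C", "G", "U", "4tU"),
                                     modifications = neutralModifications()) {
  stopifnot(maxLen >= 1L)
  if (length(alphabet) == 0L || !"4tU" %in% alphabet)
    stop("adduct alphabet must contain 4tU")
  unknown <- setdiff(alphabet, names(.NUCLEOTIDE_SPECS))
  if (length(unknown)) stop("unknown base code(s): ",
                            paste(unknown, collapse = ", "))
  comps <- list()
  for (k in seq_len(maxLen)) {
    m <- .multisets(alphabet, k)
    keep <- colSums(m == "4tU") >= 1L
    m <- m[, keep, drop = FALSE]
    comps <- c(comps, lapply(seq_len(ncol(m)), function(j) sort(m[, j])))
  }
  comps <- unique(comps)
  rows <- lapply(comps, function(comp) {
    data.frame(
      composition = paste(comp, collapse = "+"),
      modification = modifications,
      precursor_mass_da = vapply(modifications,
                                 function(mod) .adductMass(comp, mod),
                                 numeric(1)),
      row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  out$label <- ifelse(out$modification == "none", out$composition,
                      paste0(out$composition, " ", out$modification))
  out <- out[order(out$precursor_mass_da, out$label), ]
  rownames(out) <- NULL
  out[, c("label", "composition", "modification", "precursor_mass_da")]
}

#' Write / read an adduct table
#'
#' Tab-separated export of an enumerated adduct list, including the
#' shared retained-stub mass set as a semicolon-joined column.
#'
#' @param adducts A data.frame from \code{\link{enumerateTargetedAdducts}}.
#' @param path File path.
#' @return \code{readAdductTable} returns the adduct data.frame (without
#'   the stub column, which is global).
#' @export
writeAdductTable <- function(adducts, path) {
  stubs <- paste(sprintf("%.6f", retentionFragmentSet()$mass),
                 collapse = ";")
  out <- adducts
  out$retained_stub_masses <- stubs
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAdductTable
#' @export
readAdductTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("label", "composition", "modification", "precursor_mass_da")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("adduct table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab[, need]
}
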