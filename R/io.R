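#' @title Readers and writers for standard formats
#' @name io
NULL

#' Read a protein FASTA file
#'
#' Headers are parsed to the first whitespace as the identifier;
#' sequences are uppercased and validated against the 20-letter
#' alphabet. Identifiers prefixed \code{"REV_"} are flagged as decoys.
#'
#' @param path FASTA file path.
#' @return Protein record data.frame (\code{id}, \code{sequence},
#'   \code{is_decoy}).
#' @export
readFasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aas))
  for (i in seq_along(seqs)) {
    bad <- regmatches(seqs[i],
                      regexpr("[^GASPVTCLINDQKEMHFRYW]", seqs[i]))
    if (length(bad) && nzchar(bad))
      stop("illegal residue '", bad, "' in sequence ", ids[i])
    if (!nzchar(seqs[i])) stop("empty sequence for ", ids[i])
  }
  data.frame(id = ids, sequence = unname(seqs),
             is_decoy = startsWith(ids, "REV_"),
             stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' @param proteins Protein record data.frame.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return The path, invisibly.
#' @export
writeFasta <- function(proteins, path, width = 60L) {
  aas <- Biostrings::AAStringSet(proteins$sequence)
  names(aas) <- proteins$id
  Biostrings::writeXStringSet(aas, path, width = width)
  invisible(path)
}

#' Read MS2 peak lists from an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS and CHARGE
#' (both the \code{"2+"} and plain \code{"2"} dialects). Peaks are
#' sorted by m/z. Blocks missing a precursor or containing no peaks
#' are skipped with a warning and counted in the \code{"skipped"}
#' attribute.
#'
#' @param path MGF file path.
#' @return List of \linkS4class{Spectrum} objects.
#' @export
readMgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  spectra <- list()
  skipped <- 0L
  for (bi in seq_along(starts)) {
    block <- lines[(starts[bi] + 1L):(ends[bi] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pep <- grep("^PEPMASS=", block, value = TRUE)[1]
    chg <- grep("^CHARGE=", block, value = TRUE)[1]
    peakLines <- grep("^[0-9]", block, value = TRUE)
    ok <- !is.na(pep) && !is.na(chg) && length(peakLines) > 0L
    if (ok) {
      mzInt <- do.call(rbind, lapply(strsplit(peakLines, "[ \t]+"),
                                     function(x) as.numeric(x[1:2])))
      precMz <- as.numeric(strsplit(sub("^PEPMASS=", "", pep),
                                    "[ \t]+")[[1]][1])
      z <- suppressWarnings(
        as.integer(sub("\\+$", "", sub("^CHARGE=", "", chg))))
      ok <- is.finite(precMz) && !is.na(z) && !anyNA(mzInt)
      if (ok) {
        id <- if (is.na(title)) sprintf("index=%d", bi) else title
        spectra[[length(spectra) + 1L]] <-
          Spectrum(id, precMz, z, mzInt[, 1], mzInt[, 2])
      }
    }
    if (!ok) skipped <- skipped + 1L
  }
  if (skipped > 0L)
    warning(skipped, " unparseable MGF block(s) skipped")
  if (length(spectra) == 0L)
    stop("no valid spectra in MGF file: ", path)
  attr(spectra, "skipped") <- skipped
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra List of \linkS4class{Spectrum} objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp@id),
                 sprintf("PEPMASS=%.6f", sp@precursorMz),
                 sprintf("CHARGE=%d+", sp@precursorCharge),
                 sprintf("%.6f %.4f", sp@mz, sp@intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read a SILAC peptide evidence table
#'
#' Consumes the tab-separated peptides-table dialect written by the
#' upstream identification software: columns \code{Sequence},
#' \code{Leading razor protein}, \code{Intensity H <exp>} /
#' \code{Intensity L <exp>} per experiment, \code{Reverse} and
#' \code{Potential contaminant} (flagged with \code{"+"}). Zero
#' intensities are treated as missing.
#'
#' @param path File path.
#' @return Peptide evidence table: \code{sequence}, \code{protein},
#'   \code{reverse}, \code{contaminant}, and \code{H.<exp>} /
#'   \code{L.<exp>} intensity columns.
#' @export
readPeptideTable <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("Sequence", "Leading razor protein")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("peptide table missing column(s): ",
         paste(miss, collapse = ", "))
  flag <- function(col) {
    if (col %in% names(raw)) !is.na(raw[[col]]) & raw[[col]] == "+"
    else rep(FALSE, nrow(raw))
  }
  out <- data.frame(sequence = raw$Sequence,
                    protein = raw[["Leading razor protein"]],
                    reverse = flag("Reverse"),
                    contaminant = flag("Potential contaminant"),
                    stringsAsFactors = FALSE)
  hCols <- grep("^Intensity H ", names(raw), value = TRUE)
  lCols <- grep("^Intensity L ", names(raw), value = TRUE)
  if (length(hCols) == 0L || length(lCols) == 0L)
    stop("peptide table missing column(s): Intensity H/L <experiment>")
  for (cn in c(hCols, lCols)) {
    lab <- if (startsWith(cn, "Intensity H ")) "H" else "L"
    exp <- sub("^Intensity [HL] ", "", cn)
    v <- as.numeric(raw[[cn]])
    v[!is.finite(v) | v == 0] <- NA_real_
    out[[paste0(lab, ".", exp)]] <- v
  }
  out
}

#' Write a peptide evidence table in the upstream dialect
#'
#' Inverse of \code{\link{readPeptideTable}}: missing intensities are
#' written as 0, flags as \code{"+"}.
#'
#' @param table Peptide evidence table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePeptideTable <- function(table, path) {
  out <- data.frame(Sequence = table$sequence,
                    `Leading razor protein` = table$protein,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (cn in .intensityCols(table)) {
    lab <- substr(cn, 1L, 1L)
    exp <- sub("^[HL]\\.", "", cn)
    v <- table[[cn]]
    v[!is.finite(v)] <- 0
    out[[paste("Intensity", lab, exp)]] <- v
  }
  out$Reverse <- ifelse(table$reverse, "+", "")
  out[["Potential contaminant"]] <- ifelse(table$contaminant, "+", "")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an experiment design file
#'
#' Two tab-separated columns: \code{experiment}, \code{orientation}
#' (forward/reverse).
#'
#' @param path File path.
#' @return A \code{\link{silacDesign}} vector.
#' @export
readDesignFile <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("experiment", "orientation")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("design file missing column(s): ",
         paste(miss, collapse = ", "))
  silacDesign(tab$experiment, tab$orientation)
}

#' Read a phosphosite annotation table
#'
#' Two tab-separated columns: \code{protein}, \code{position}
#' (1-based). Duplicate positions per protein are collapsed.
#'
#' @param path File path.
#' @return Named list protein -> sorted integer positions.
#' @export
readPhosphoTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "position")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("phosphosite table missing column(s): ",
         paste(miss, collapse = ", "))
  lapply(split(as.integer(tab$position), tab$protein),
         function(p) sort(unique(p)))
}
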