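# Reference-anchored motif and residue conservation over an MSA, with the
# canonical dehydratase (NisB-numbered) and cyclase (NisC-numbered) motif
# sets shipped as package data.

#' Map alignment columns to reference residue numbers
#'
#' @param m an [Biostrings::AAMultipleAlignment].
#' @param referenceId row name of the reference sequence.
#' @return list with `colToRes` (integer per column: number of reference
#'   residues at or before that column; 0 before the first) and `resToCol`
#'   (column index of each reference residue, 1-based).
#' @export
mapToReference <- function(m, referenceId) {
  x <- as.character(unmasked(m))
  if (!referenceId %in% names(x)) stop("unknown reference id: ", referenceId)
  ch <- strsplit(x[[referenceId]], "", fixed = TRUE)[[1L]]
  nonGap <- ch != "-"
  colToRes <- cumsum(nonGap)
  resToCol <- which(nonGap)
  list(colToRes = colToRes, resToCol = resToCol)
}

#' Motif definitions for a reference-anchored conservation table
#'
#' @param pattern character vector of patterns over amino-acid letters and
#'   the wildcard `x` (e.g. `"CHG"`, `"GxAHGxxG"`).
#' @param start reference residue number of the first pattern position.
#' @param name optional motif names (default: the patterns).
#' @return [S4Vectors::DataFrame] with `name`, `pattern`, `ref_start`,
#'   `ref_end` (`ref_end = ref_start + nchar(pattern) - 1`).
#' @export
motifDefinition <- function(pattern, start, name = pattern) {
  DataFrame(name = name, pattern = pattern, ref_start = as.integer(start),
            ref_end = as.integer(start + nchar(pattern) - 1L))
}

#' Canonical dehydratase (LanB) motif set, NisB numbering
#'
#' The conserved motifs of type 1 lanthionine dehydratases anchored to
#' NisB residue numbers: YxxR (80), RxTPFG (89), FxxxYG (342), GxG (363),
#' GRF (463), PxxxRxxNV (501), RFL (585), RYG (826), HxxxNR (961).
#'
#' @return a motif [S4Vectors::DataFrame] (see [motifDefinition()]).
#' @export
nisbMotifs <- function() {
  motifDefinition(
    pattern = c("YxxR", "RxTPFG", "FxxxYG", "GxG", "GRF", "PxxxRxxNV",
                "RFL", "RYG", "HxxxNR"),
    start = c(80L, 89L, 342L, 363L, 463L, 501L, 585L, 826L, 961L))
}

#' Canonical dehydratase (LanB) single-residue set, NisB numbering
#' @return a motif [S4Vectors::DataFrame] of single-residue patterns.
#' @export
nisbResidues <- function() {
  motifDefinition(
    pattern = c("R", "D", "N", "L", "D", "V", "P", "W", "P", "D", "D",
                "F", "E"),
    start = c(14L, 121L, 145L, 217L, 299L, 352L, 612L, 616L, 639L, 648L,
              843L, 840L, 975L),
    name = c("R14", "D121", "N145", "L217", "D299", "V352", "P612",
             "W616", "P639", "D648", "D843", "F840", "E975"))
}

#' Canonical cyclase (LanC) motif set, NisC numbering
#'
#' LxxG (39), YDxxxGxxG (140), GxAHGxxG (209), WCYG (283), CHG (330),
#' GxxxGxxGxxLxL (377). The CHG cysteine/histidine are the active-site
#' zinc ligands.
#'
#' @return a motif [S4Vectors::DataFrame].
#' @export
niscMotifs <- function() {
  motifDefinition(
    pattern = c("LxxG", "YDxxxGxxG", "GxAHGxxG", "WCYG", "CHG",
                "GxxxGxxGxxLxL"),
    start = c(39L, 140L, 209L, 283L, 330L, 377L))
}

#' Canonical cyclase (LanC) single-residue set, NisC numbering
#' @return a motif [S4Vectors::DataFrame] of single-residue patterns.
#' @export
niscResidues <- function() {
  motifDefinition(pattern = c("G", "W", "W"),
                  start = c(90L, 258L, 401L),
                  name = c("G90", "W258", "W401"))
}

#' Motif conservation over an alignment
#'
#' For each motif, the reference residues `ref_start..ref_end` are mapped
#' to alignment columns; a row contains the motif when its characters at
#' every non-wildcard column equal the pattern letters. Percent
#' conservation is over all rows (the reference included), rounded to the
#' nearest integer.
#'
#' @param m an [Biostrings::AAMultipleAlignment].
#' @param defs motif [S4Vectors::DataFrame] (see [motifDefinition()]).
#' @param referenceId row name anchoring the numbering.
#' @param breakdown if `TRUE`, also return per-letter conservation for
#'   each non-wildcard position of every motif (partial-motif reporting).
#' @return [S4Vectors::DataFrame]: `name`, `pattern`, `ref_start`,
#'   `ref_end`, `percent_conserved`, `n_sequences` (plus `letter` rows if
#'   `breakdown`).
#' @export
motifConservation <- function(m, defs, referenceId, breakdown = FALSE) {
  mat <- msaMatrix(m)
  map <- mapToReference(m, referenceId)
  refLen <- length(map$resToCol)
  n <- nrow(mat)
  main <- list()
  extra <- list()
  for (i in seq_len(nrow(defs))) {
    pat <- strsplit(defs$pattern[i], "", fixed = TRUE)[[1L]]
    rs <- defs$ref_start[i]; re <- defs$ref_end[i]
    if (rs < 1L || re > refLen)
      stop("motif ", defs$name[i], " positions ", rs, "-", re,
           " outside reference length ", refLen)
    cols <- map$resToCol[rs:re]
    anchored <- pat != "x"
    sub <- mat[, cols, drop = FALSE]
    hasAll <- rep(TRUE, n)
    for (p in which(anchored)) hasAll <- hasAll & sub[, p] == pat[p]
    main[[i]] <- DataFrame(name = defs$name[i], pattern = defs$pattern[i],
                           ref_start = rs, ref_end = re,
                           percent_conserved = round(100 * sum(hasAll) / n),
                           n_sequences = n)
    if (breakdown && sum(anchored) > 1L) {
      for (p in which(anchored)) {
        extra[[length(extra) + 1L]] <- DataFrame(
          name = sprintf("%s:%s%d", defs$name[i], pat[p], rs + p - 1L),
          pattern = pat[p], ref_start = rs + p - 1L, ref_end = rs + p - 1L,
          percent_conserved = round(100 * sum(sub[, p] == pat[p]) / n),
          n_sequences = n)
      }
    }
  }
  out <- do.call(rbind, c(main, extra))
  rownames(out) <- NULL
  out
}

#' Single-residue conservation over an alignment
#'
#' Conservation of the reference's residue (or a supplied letter) at given
#' reference positions; a convenience wrapper over [motifConservation()]
#' with single-column patterns.
#'
#' @param m an [Biostrings::AAMultipleAlignment].
#' @param positions reference residue numbers.
#' @param referenceId row anchoring the numbering.
#' @param letters expected letters; default: the reference's own residues.
#' @return [S4Vectors::DataFrame] as in [motifConservation()].
#' @export
residueConservation <- function(m, positions, referenceId, letters = NULL) {
  map <- mapToReference(m, referenceId)
  if (is.null(letters)) {
    ref <- aaChars(ungapRow(m, referenceId))
    letters <- ref[positions]
  }
  defs <- motifDefinition(pattern = letters, start = positions,
                          name = sprintf("%s%d", letters, positions))
  motifConservation(m, defs, referenceId)
}

#' Write a conservation table as TSV
#'
#' @param tab DataFrame from [motifConservation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConservationTable <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
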