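# Genome access: translation, proteome extraction, intergenic regions.

BACTERIAL_STARTS <- c("ATG", "GTG", "TTG")

# Translate a CDS given 0-based half-open coordinates on `dna`.
# `parts` is an optional k x 2 matrix of 0-based half-open sub-intervals
# (GenBank join()); they are concatenated in ascending order before the
# strand flip, matching GenBank semantics for complement(join(...)).
translateCDS <- function(dna, start, end, strand, parts = NULL) {
  if (is.null(parts)) parts <- matrix(c(start, end), ncol = 2L)
  parts <- parts[order(parts[, 1L]), , drop = FALSE]
  segs <- lapply(seq_len(nrow(parts)), function(i)
    subseq(dna, start = parts[i, 1L] + 1L, end = parts[i, 2L]))
  cds <- do.call(xscat, segs)
  if (strand < 0L) cds <- reverseComplement(cds)
  n <- length(cds)
  if (n < 3L) return("")
  n <- n - (n %% 3L)
  cds <- subseq(cds, 1L, n)
  aa <- as.character(suppressWarnings(
    translate(cds, if.fuzzy.codon = "solve")))
  aa <- chartr("*", "*", aa)
  # drop the trailing stop, keep (and tolerate) internal stops
  if (substring(aa, nchar(aa)) == "*") aa <- substring(aa, 1L, nchar(aa) - 1L)
  startCodon <- as.character(subseq(cds, 1L, 3L))
  if (nchar(aa) >= 1L && startCodon %in% BACTERIAL_STARTS)
    substring(aa, 1L, 1L) <- "M"
  if (grepl("*", aa, fixed = TRUE))
    message("internal stop codon(s) in translation (kept as '*')")
  aa
}

#' Extract the annotated proteome of a genome
#'
#' Returns one protein per CDS feature, in feature (start-coordinate) order.
#' Features lacking a stored translation are translated from their
#' coordinates. Ambiguous codons translate to `X`.
#'
#' @param g a [GenomeRecord-class].
#' @return an [Biostrings::AAStringSet] named by locus tag, with `mcols`
#'   columns `genome` and `locus_tag`.
#' @export
extractProteome <- function(g) {
  f <- features(g)
  if (nrow(f) == 0L) {
    out <- AAStringSet()
    mcols(out) <- DataFrame(genome = character(), locus_tag = character())
    return(out)
  }
  aa <- vapply(seq_len(nrow(f)), function(i) {
    tr <- f$translation[i]
    if (!is.na(tr) && nzchar(tr)) tr
    else translateCDS(genomeSequence(g), f$start[i], f$end[i], f$strand[i])
  }, character(1))
  out <- AAStringSet(aa)
  names(out) <- f$locus_tag
  mcols(out) <- DataFrame(genome = accession(g), locus_tag = f$locus_tag)
  out
}

#' Maximal CDS-free intervals of a genome
#'
#' Computes the maximal intervals not covered by any CDS on either strand,
#' tagged with the flanking locus tags. For circular genomes the gap
#' spanning the origin is reported as a single region whose `end` exceeds
#' the genome length (`wraps = TRUE`).
#'
#' @param g a [GenomeRecord-class].
#' @param minLen minimum region length in nucleotides (default 1).
#' @return a [S4Vectors::DataFrame] with columns `genome`, `start`, `end`
#'   (0-based half-open), `flank_left`, `flank_right`, `wraps`.
#' @export
intergenicRegions <- function(g, minLen = 1L) {
  stopifnot(minLen >= 0L)
  L <- length(g)
  f <- features(g)
  empty <- DataFrame(genome = character(), start = integer(),
                     end = integer(), flank_left = character(),
                     flank_right = character(), wraps = logical())
  if (nrow(f) == 0L) {
    if (L < max(minLen, 1L)) return(empty)
    return(DataFrame(genome = accession(g), start = 0L, end = L,
                     flank_left = NA_character_, flank_right = NA_character_,
                     wraps = FALSE))
  }
  cds <- IRanges(start = f$start + 1L, end = f$end)  # 1-based for IRanges
  free <- gaps(reduce(cds), start = 1L, end = L)
  st <- start(free) - 1L
  en <- end(free)
  wraps <- rep(FALSE, length(free))
  if (topology(g) == "circular" && length(free) >= 2L &&
      st[1L] == 0L && en[length(en)] == L) {
    # merge the two origin-adjacent gaps into one wrap-around region
    st <- c(st[-1L])
    en[length(en)] <- L + end(free)[1L]
    en <- en[-1L]
    wraps <- rep(FALSE, length(st))
    wraps[length(wraps)] <- TRUE
  }
  keep <- (en - st) >= minLen
  st <- st[keep]; en <- en[keep]; wraps <- wraps[keep]
  if (!length(st)) return(empty)
  flankLeft <- vapply(st, function(s) {
    i <- which(f$end <= ((s - 1L) %% L) + 1L)
    if (length(i)) f$locus_tag[i[which.max(f$end[i])]] else NA_character_
  }, character(1))
  flankRight <- vapply(en, function(e) {
    i <- which(f$start >= (e %% L))
    if (length(i)) f$locus_tag[i[which.min(f$start[i])]] else
      f$locus_tag[which.min(f$start)]
  }, character(1))
  DataFrame(genome = accession(g), start = as.integer(st),
            end = as.integer(en), flank_left = flankLeft,
            flank_right = flankRight, wraps = wraps)
}

# Fetch the nucleotide sequence of a (possibly wrap-around) region.
regionSequence <- function(g, start, end) {
  L <- length(g)
  if (end <= L) return(subseq(genomeSequence(g), start + 1L, end))
  xscat(subseq(genomeSequence(g), start + 1L, L),
        subseq(genomeSequence(g), 1L, end - L))
}
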