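# LanA precursor discovery: six-frame ORF finding in intergenic DNA and
# composition-based scoring of candidate prepropeptides.

#' LanA scoring configuration
#'
#' Defaults: length 20-120 aa (type 1 precursors centre around ~60 aa but
#' known examples span roughly 43-86), at least one cysteine, propeptide
#' S+T+C fraction >= 0.35 and propeptide-minus-leader S+T+C skew >= 0.04.
#' The fraction threshold carries most of the specificity (random peptides
#' rarely reach 0.35 in their best propeptide window) while the skew
#' threshold enforces the direction of the bias; both were calibrated so
#' that the packaged nisin/subtilin/epidermin/gallidermin precursors pass
#' and random same-length peptides pass at under 5 percent. The
#' leader/propeptide split is searched over the central 25-75% of the
#' peptide, with leader >= 6 aa and propeptide >= 10 aa.
#'
#' @param minAA,maxAA length bounds (amino acids).
#' @param stcFractionMin minimum propeptide S+T+C fraction.
#' @param stcSkewMin minimum S+T+C skew (propeptide minus leader density).
#' @param minLeader,minPropeptide split-search bounds.
#' @return a [LanaConfig-class].
#' @export
lanaConfig <- function(minAA = 20L, maxAA = 120L, stcFractionMin = 0.35,
                       stcSkewMin = 0.04, minLeader = 6L,
                       minPropeptide = 10L) {
  new("LanaConfig", minAA = as.integer(minAA), maxAA = as.integer(maxAA),
      stcFractionMin = stcFractionMin, stcSkewMin = stcSkewMin,
      minLeader = as.integer(minLeader),
      minPropeptide = as.integer(minPropeptide))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs in the three frames of one strand of `s` (character). Returns a
# list of equal-length vectors with 0-based half-open coords on `s`;
# peptides are only built when `translate` is TRUE.
orfsOneStrand <- function(s, minAA, maxAA, translate = TRUE) {
  n <- nchar(s)
  start <- integer(); end <- integer(); frame <- integer()
  peptide <- character()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    at <- seq(f + 1L, by = 3L, length.out = ncod)
    codons <- substring(s, at, at + 2L)
    isStop <- codons %in% STOP_CODONS
    isStart <- codons %in% BACTERIAL_STARTS
    stopIdx <- which(isStop)
    if (!length(stopIdx)) next
    # first start codon strictly after the preceding stop, per stop
    startIdx <- which(isStart)
    if (!length(startIdx)) next
    prevStop <- c(0L, stopIdx[-length(stopIdx)])
    pos <- findInterval(prevStop, startIdx) + 1L
    ok <- pos <= length(startIdx)
    a <- ifelse(ok, startIdx[pmin(pos, length(startIdx))], NA_integer_)
    lenAA <- stopIdx - a
    keep <- which(ok & !is.na(a) & a < stopIdx &
                    lenAA >= minAA & lenAA <= maxAA)
    if (!length(keep)) next
    peps <- if (translate) vapply(keep, function(k) {
      pep <- paste(GENCODE[codons[a[k]:(stopIdx[k] - 1L)]], collapse = "")
      substring(pep, 1L, 1L) <- "M"
      pep
    }, character(1)) else character(length(keep))
    start <- c(start, f + 3L * (a[keep] - 1L))
    end <- c(end, f + 3L * stopIdx[keep])  # includes the stop codon
    frame <- c(frame, rep(f, length(keep)))
    peptide <- c(peptide, peps)
  }
  list(start = start, end = end, frame = frame, peptide = peptide)
}

revcompChr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# lean six-frame scan used by the background generator: coordinates only.
fastOrfScan <- function(s, minAA, maxAA = .Machine$integer.max) {
  n <- nchar(s)
  fwd <- orfsOneStrand(s, minAA, maxAA, translate = FALSE)
  rev <- orfsOneStrand(revcompChr(s), minAA, maxAA, translate = FALSE)
  list(start = c(fwd$start, n - rev$end),
       end = c(fwd$end, n - rev$start),
       strand = rep(c(1L, -1L), c(length(fwd$start), length(rev$start))))
}

# codon -> single letter lookup (standard code, unknown -> X)
GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})

#' Six-frame ORF scan
#'
#' Finds every maximal start-to-stop open reading frame in all six frames
#' whose peptide length (stop excluded) lies in `[minAA, maxAA]`. Start
#' codons ATG/GTG/TTG are accepted and translated as Met; an ORF is maximal
#' when its start is the first start codon after the preceding in-frame
#' stop. Coordinates are 0-based half-open on the input sequence and cover
#' start codon through stop codon; `frame` is the frame (0/1/2) on the
#' scanned strand.
#'
#' @param dna character or [Biostrings::DNAString].
#' @param minAA minimum peptide length (>= 10).
#' @param maxAA maximum peptide length.
#' @return [S4Vectors::DataFrame] with columns `start`, `end`, `strand`,
#'   `frame`, `peptide`.
#' @export
sixFrameOrfs <- function(dna, minAA = 20L, maxAA = 120L) {
  stopifnot(minAA >= 10L)
  s <- toupper(as.character(dna))
  n <- nchar(s)
  empty <- DataFrame(start = integer(), end = integer(), strand = integer(),
                     frame = integer(), peptide = character())
  if (n < 3L * minAA) return(empty)
  fwd <- orfsOneStrand(s, minAA, maxAA)
  rev <- orfsOneStrand(revcompChr(s), minAA, maxAA)
  out <- DataFrame(
    start = c(fwd$start, n - rev$end),
    end = c(fwd$end, n - rev$start),
    strand = rep(c(1L, -1L), c(length(fwd$start), length(rev$start))),
    frame = c(fwd$frame, rev$frame),
    peptide = c(fwd$peptide, rev$peptide))
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

stcCount <- function(chars) sum(chars %in% c("S", "T", "C"))

allowedSplits <- function(L, cfg) {
  lo <- max(cfg@minLeader, floor(0.25 * L))
  hi <- min(L - cfg@minPropeptide, ceiling(0.75 * L))
  if (hi < lo) return(integer())
  seq.int(lo, hi)
}

#' Split a prepropeptide into leader and propeptide
#'
#' Chooses the split index maximizing the difference in S+T+C density
#' between the C-terminal propeptide and the N-terminal leader, searched
#' over the central window of allowed split positions (see [lanaConfig()]).
#' Ties break to the smallest index.
#'
#' @param peptide amino-acid string (length >= 20).
#' @param cfg a [LanaConfig-class].
#' @return list with `split_index` (leader = `peptide[1..split_index]`),
#'   `skew`, `stc_fraction_propeptide`, `method = "heuristic"`.
#' @export
splitLeader <- function(peptide, cfg = lanaConfig()) {
  peptide <- as.character(peptide)
  L <- nchar(peptide)
  stopifnot(L >= 20L)
  ch <- aaChars(peptide)
  stc <- cumsum(ch %in% c("S", "T", "C"))
  total <- stc[L]
  idx <- allowedSplits(L, cfg)
  if (!length(idx)) idx <- max(1L, min(L - 1L, L %/% 2L))
  skew <- (total - stc[idx]) / (L - idx) - stc[idx] / idx
  best <- idx[which.max(skew)]  # which.max takes the first maximum
  list(split_index = best,
       skew = max(skew),
       stc_fraction_propeptide = (total - stc[best]) / (L - best),
       method = "heuristic")
}

#' Score a peptide against the LanA precursor criteria
#'
#' A candidate passes when its length is within bounds, it contains at
#' least one cysteine, its propeptide S+T+C fraction reaches
#' `stcFractionMin` and its S+T+C skew (propeptide minus leader density at
#' the optimal split) reaches `stcSkewMin`. Motifs add to the composite
#' rank score (`2 * skew + 0.1 * min(cys, 10)` + bonuses) without being
#' required: +1 for a DLD box in the N-terminal half (the conserved
#' leader motif), +0.5 for a leucine in the late-leader zone, +0.5 for a
#' cysteine pair spaced 2-4 apart in the C-terminal half (CTPGC-like).
#'
#' @param peptide amino-acid string.
#' @param cfg a [LanaConfig-class].
#' @return list: `length_aa`, `cys_count`, `split_index`,
#'   `stc_fraction_propeptide`, `stc_skew`, `leader_motif_hits` (character),
#'   `composite`, `passes`.
#' @export
scoreLana <- function(peptide, cfg = lanaConfig()) {
  peptide <- as.character(peptide)
  L <- nchar(peptide)
  if (L == 0L) stop("peptide must be non-empty")
  ch <- aaChars(peptide)
  cys <- sum(ch == "C")
  if (L < 20L) {
    return(list(length_aa = L, cys_count = cys, split_index = NA_integer_,
                stc_fraction_propeptide = NA_real_, stc_skew = NA_real_,
                leader_motif_hits = character(), composite = -Inf,
                passes = FALSE))
  }
  sp <- splitLeader(peptide, cfg)
  # motif bonuses live in fixed windows (N-terminal half for leader
  # motifs, C-terminal half for the cysteine pair) so the composite is
  # independent of where the density split lands
  nTermHalf <- substr(peptide, 1L, ceiling(L / 2))
  cTermHalf <- substring(peptide, floor(L / 2))
  motifs <- character()
  bonus <- 0
  if (grepl("DLD", nTermHalf, fixed = TRUE)) {
    motifs <- c(motifs, "DLD")
    bonus <- bonus + 1
  }
  leuZone <- substr(peptide, max(1L, floor(0.25 * L)), ceiling(L / 2))
  if (grepl("L", leuZone, fixed = TRUE)) {
    motifs <- c(motifs, "leaderLeu")
    bonus <- bonus + 0.5
  }
  if (grepl("C.{2,4}C", cTermHalf)) {
    motifs <- c(motifs, "CxxC")
    bonus <- bonus + 0.5
  }
  composite <- 2 * sp$skew + 0.1 * min(cys, 10L) + bonus
  passes <- (L >= cfg@minAA && L <= cfg@maxAA) && cys >= 1L &&
    sp$stc_fraction_propeptide >= cfg@stcFractionMin &&
    sp$skew >= cfg@stcSkewMin
  list(length_aa = L, cys_count = cys, split_index = sp$split_index,
       stc_fraction_propeptide = sp$stc_fraction_propeptide,
       stc_skew = sp$skew, leader_motif_hits = motifs,
       composite = composite, passes = passes)
}

lanaScoreRow <- function(peptide, cfg) {
  s <- scoreLana(peptide, cfg)
  DataFrame(length_aa = s$length_aa, cys_count = s$cys_count,
            split_index = s$split_index,
            stc_fraction_propeptide = s$stc_fraction_propeptide,
            stc_skew = s$stc_skew,
            leader_motifs = paste(s$leader_motif_hits, collapse = ";"),
            composite = s$composite, passes = s$passes)
}

#' Find LanA candidates near LanB/LanC anchors
#'
#' Scores every annotated CDS and every intergenic six-frame ORF within
#' `windowNt` of an anchor hit against the LanA criteria, returning the
#' passing candidates sorted by composite score (descending). Annotated
#' candidates carry provenance `"annotated"`, intergenic ORFs
#' `"intergenic"`. Anchor genes themselves are excluded.
#'
#' @param g a [GenomeRecord-class].
#' @param anchors hits DataFrame (from [screenProteome()] /
#'   [iterativeExpand()]) restricted to `g`; only `locus_tag` is used to
#'   locate anchors.
#' @param windowNt search window on either side of an anchor (default
#'   10000).
#' @param cfg a [LanaConfig-class].
#' @return [S4Vectors::DataFrame]: `id`, `start`, `end`, `strand`,
#'   `provenance`, `peptide`, plus the [scoreLana()] columns.
#' @export
findLanaCandidates <- function(g, anchors, windowNt = 10000L,
                               cfg = lanaConfig()) {
  out <- list()
  if (is.null(anchors) || nrow(anchors) == 0L) {
    e <- DataFrame(id = character(), start = integer(), end = integer(),
                   strand = integer(), provenance = character(),
                   peptide = character())
    return(cbind(e, lanaScoreRow("A", cfg)[0L, , drop = FALSE]))
  }
  f <- features(g)
  anchorTags <- unique(anchors$locus_tag)
  ai <- match(anchorTags, f$locus_tag)
  ai <- ai[!is.na(ai)]
  wStart <- pmax(0L, f$start[ai] - windowNt)
  wEnd <- pmin(length(g), f$end[ai] + windowNt)
  inWindow <- function(s, e)
    any(s < wEnd & e > wStart)
  # annotated CDS in window (excluding anchors)
  for (i in seq_len(nrow(f))) {
    if (f$locus_tag[i] %in% anchorTags) next
    if (!inWindow(f$start[i], f$end[i])) next
    pep <- f$translation[i]
    if (is.na(pep) || !nzchar(pep)) next
    if (nchar(pep) > cfg@maxAA) next
    row <- lanaScoreRow(pep, cfg)
    if (!row$passes) next
    out[[length(out) + 1L]] <- cbind(
      DataFrame(id = f$locus_tag[i], start = f$start[i], end = f$end[i],
                strand = f$strand[i], provenance = "annotated",
                peptide = pep), row)
  }
  # intergenic ORFs in window
  ig <- intergenicRegions(g, minLen = 3L * cfg@minAA)
  for (i in seq_len(nrow(ig))) {
    if (!inWindow(ig$start[i], ig$end[i])) next
    seqI <- regionSequence(g, ig$start[i], ig$end[i])
    orfs <- sixFrameOrfs(seqI, minAA = cfg@minAA, maxAA = cfg@maxAA)
    for (k in seq_len(nrow(orfs))) {
      oStart <- ig$start[i] + orfs$start[k]
      oEnd <- ig$start[i] + orfs$end[k]
      if (!inWindow(oStart, oEnd)) next
      row <- lanaScoreRow(orfs$peptide[k], cfg)
      if (!row$passes) next
      out[[length(out) + 1L]] <- cbind(
        DataFrame(id = sprintf("%s_orf_%d_%d", accession(g), oStart, oEnd),
                  start = oStart, end = oEnd, strand = orfs$strand[k],
                  provenance = "intergenic", peptide = orfs$peptide[k]),
        row)
    }
  }
  if (!length(out)) {
    e <- DataFrame(id = character(), start = integer(), end = integer(),
                   strand = integer(), provenance = character(),
                   peptide = character())
    return(cbind(e, lanaScoreRow("A", cfg)[0L, , drop = FALSE]))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$composite, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
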