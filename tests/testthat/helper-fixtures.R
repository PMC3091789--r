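# Shared fixtures: tiny sequence generators and reference peptides.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
        "M", "F", "P", "S", "T", "W", "Y", "V")

NISA <- "MSTKDFNLDLVSVSKKDSGASPRITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK"

randProt <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

# a small hand-built genome: two CDS on opposite strands with a gap
toyGenome <- function() {
  # CDS1 (+): ATG AAA TGC TAA  -> MKC
  # CDS2 (-): revcomp(ATG GGT TTT TAA) -> MGF
  cds1 <- "ATGAAATGCTAA"
  cds2 <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGGGTTTTTAA")))
  seqn <- paste0("TTTTT", cds1, "ACGTACGTAC", cds2, "GGGGG")
  feats <- S4Vectors::DataFrame(
    locus_tag = c("T_0001", "T_0002"),
    start = c(5L, 5L + 12L + 10L),
    end = c(17L, 5L + 12L + 10L + 12L),
    strand = c(1L, -1L),
    translation = c("MKC", "MGF"),
    product = c("p1", "p2"))
  GenomeRecord("TOY00001", seqn, feats)
}

# brute-force maximal-ORF oracle: tests every position on both strands,
# walks forward to the next in-frame stop, and checks maximality by
# walking backwards. Independent of the package's scanning logic.
bruteOrfs <- function(dna, minAA, maxAA) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  scan1 <- function(s) {
    n <- nchar(s)
    out <- list()
    for (p in seq_len(n - 2L)) {
      if (!substr(s, p, p + 2L) %in% starts) next
      # maximality: walk back; a start before a stop means not maximal
      maximal <- TRUE
      q <- p - 3L
      while (q >= 1L) {
        cod <- substr(s, q, q + 2L)
        if (cod %in% stops) break
        if (cod %in% starts) { maximal <- FALSE; break }
        q <- q - 3L
      }
      if (!maximal) next
      # walk forward to the stop
      q <- p + 3L
      stopAt <- NA_integer_
      while (q + 2L <= n) {
        if (substr(s, q, q + 2L) %in% stops) { stopAt <- q; break }
        q <- q + 3L
      }
      if (is.na(stopAt)) next
      lenAA <- (stopAt - p) %/% 3L
      if (lenAA < minAA || lenAA > maxAA) next
      out[[length(out) + 1L]] <- c(p - 1L, stopAt + 2L)  # 0-based half-open
    }
    out
  }
  n <- nchar(dna)
  fwd <- scan1(dna)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  rev <- scan1(rc)
  rows <- rbind(
    if (length(fwd)) cbind(do.call(rbind, fwd), 1L),
    if (length(rev)) {
      m <- do.call(rbind, rev)
      cbind(n - m[, 2L], n - m[, 1L], -1L)
    })
  if (is.null(rows)) return(rows)
  rows[order(rows[, 1L], rows[, 2L], rows[, 3L]), , drop = FALSE]
}
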