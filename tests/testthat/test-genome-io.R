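test_that("a minimal GenBank record parses with coordinates and translation", {
  txt <- c(
    "LOCUS       MINI0001                20 bp    DNA     linear   BCT 01-JAN-2000",
    "ACCESSION   MINI0001",
    "FEATURES             Location/Qualifiers",
    "     source          1..20",
    "     CDS             3..11",
    "                     /locus_tag=\"MINI_0001\"",
    "ORIGIN",
    "        1 ccatgaaata acgtacgtac",
    "//")
  f <- tempfile(fileext = ".gbk")
  writeLines(txt, f)
  g <- readGenBank(f)
  expect_s4_class(g, "GenomeRecord")
  expect_equal(length(g), 20L)
  ft <- features(g)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$start, 2L)   # 1-based inclusive 3..11 -> 0-based [2, 11)
  expect_equal(ft$end, 11L)
  expect_equal(ft$translation, "MK")  # ATG AAA TAA, stop dropped
})

test_that("complement and join locations resolve and features come back sorted", {
  # gene on the minus strand: forward DNA holds revcomp(ATGGGTTTTTAA)
  rcg <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGGGTTTTTAA")))
  dna <- paste0("AC", rcg, "ATGAAATAA", "G")
  txt <- c(
    "LOCUS       MINI0002                24 bp    DNA     linear   BCT 01-JAN-2000",
    "ACCESSION   MINI0002",
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             %d..%d", 2L + 12L + 1L, 2L + 12L + 9L),
    "                     /locus_tag=\"B\"",
    "     CDS             complement(3..14)",
    "                     /locus_tag=\"A\"",
    "ORIGIN",
    paste0("        1 ", tolower(dna)),
    "//")
  f <- tempfile(fileext = ".gbk")
  writeLines(txt, f)
  g <- readGenBank(f)
  ft <- features(g)
  expect_equal(ft$locus_tag, c("A", "B"))        # re-sorted by start
  expect_equal(ft$strand, c(-1L, 1L))
  expect_equal(ft$translation, c("MGF", "MK"))

  # join() across two exons
  txt2 <- c(
    "LOCUS       MINI0003                30 bp    DNA     linear   BCT 01-JAN-2000",
    "ACCESSION   MINI0003",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..6,10..15)",
    "                     /locus_tag=\"J\"",
    "ORIGIN",
    "        1 atgaaaccca tgtgcTAAgg ggggggggg",
    "//")
  writeLines(txt2, f)
  g2 <- readGenBank(f)
  expect_equal(features(g2)$translation, "MKMC")  # ATG AAA | TGT GC? -> join
})

test_that("GenBank write/read round trip is the identity on all fields", {
  gen <- generateGenome(genomeSpec(seed = 31, lengthNt = 80000,
                                   nComplete = 1, decoyGeneCount = 2))
  f <- tempfile(fileext = ".gbk")
  writeGenBank(gen$genome, f)
  g2 <- readGenBank(f)
  expect_equal(accession(g2), accession(gen$genome))
  expect_equal(as.character(genomeSequence(g2)),
               as.character(genomeSequence(gen$genome)))
  a <- as.data.frame(features(gen$genome))
  b <- as.data.frame(features(g2))
  expect_equal(b[c("locus_tag", "start", "end", "strand", "translation")],
               a[c("locus_tag", "start", "end", "strand", "translation")])
})

test_that("extractProteome returns one protein per CDS in feature order", {
  g0 <- GenomeRecord("EMPTY001", randDna(300))
  expect_length(extractProteome(g0), 0L)
  g <- toyGenome()
  p <- extractProteome(g)
  expect_equal(names(p), c("T_0001", "T_0002"))
  expect_equal(as.character(p), c(T_0001 = "MKC", T_0002 = "MGF"))
  expect_equal(S4Vectors::mcols(p)$genome, rep("TOY00001", 2))
  # generator genomes: proteome must match the ground-truth proteins
  gen <- generateGenome(genomeSpec(seed = 7, lengthNt = 80000,
                                   nComplete = 1, decoyGeneCount = 1))
  p2 <- extractProteome(gen$genome)
  el <- gen$truth$elements
  el <- el[el$annotated, ]
  expect_equal(unname(as.character(p2)[el$locus_tag]), el$protein)
})

test_that("intergenic regions match a per-base occupancy oracle and tile the genome", {
  set.seed(41)
  for (rep in 1:12) {
    L <- sample(300:900, 1)
    n <- sample(1:6, 1)
    st <- sort(sample(0:(L - 30L), n))
    en <- pmin(st + sample(15:60, n, replace = TRUE), L)
    keep <- c(TRUE, st[-1] >= head(en, -1))  # non-overlapping subset
    st <- st[keep]; en <- en[keep]
    f <- S4Vectors::DataFrame(locus_tag = sprintf("G%02d", seq_along(st)),
                              start = st, end = en,
                              strand = rep(1L, length(st)),
                              translation = NA_character_,
                              product = NA_character_)
    g <- GenomeRecord("OCC00001", randDna(L), f)
    ig <- intergenicRegions(g, minLen = 1L)
    occ <- rep(FALSE, L)
    for (i in seq_along(st)) occ[(st[i] + 1):en[i]] <- TRUE
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    expStart <- starts[!r$values]
    expEnd <- ends[!r$values]
    expect_equal(ig$start, expStart)
    expect_equal(ig$end, expEnd)
    # CDS and intergenic intervals partition the genome
    covered <- sum(en - st) + sum(ig$end - ig$start)
    expect_equal(covered, L)
  }
  # genome fully covered by CDS
  full <- GenomeRecord("OCC00002", "ATGAAATAG",
                       S4Vectors::DataFrame(locus_tag = "X", start = 0L,
                                            end = 9L, strand = 1L,
                                            translation = "MK",
                                            product = NA_character_))
  expect_equal(nrow(intergenicRegions(full)), 0L)
})

test_that("flanking locus tags and the two-CDS textbook case are right", {
  f <- S4Vectors::DataFrame(locus_tag = c("L1", "L2"),
                            start = c(0L, 100L), end = c(9L, 109L),
                            strand = c(1L, 1L),
                            translation = NA_character_,
                            product = NA_character_)
  g <- GenomeRecord("FLANK001", randDna(200), f)
  ig <- intergenicRegions(g)
  expect_equal(ig$start, c(9L, 109L))
  expect_equal(ig$end, c(100L, 200L))
  expect_equal(ig$flank_left, c("L1", "L2"))
  expect_equal(ig$flank_right[1], "L2")
})
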