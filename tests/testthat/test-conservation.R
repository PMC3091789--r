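toyMsa <- function(rows) {
  x <- Biostrings::AAStringSet(rows)
  Biostrings::AAMultipleAlignment(x)
}

test_that("reference mapping handles gap-free rows, leading gaps and random MSAs", {
  m <- toyMsa(c(ref = "ACDEF", s2 = "ACDEF"))
  map <- mapToReference(m, "ref")
  expect_equal(map$resToCol, 1:5)
  m2 <- toyMsa(c(ref = "--CDEF", s2 = "AACDEF"))
  expect_equal(mapToReference(m2, "ref")$resToCol, 3:6)
  expect_error(mapToReference(m2, "nope"), "unknown")
  set.seed(31)
  for (rep in 1:10) {
    L <- 40
    ch <- sample(c(AA, "-"), L, replace = TRUE, prob = c(rep(1, 20), 5))
    row <- paste(ch, collapse = "")
    m3 <- toyMsa(c(ref = row, other = paste(sample(AA, L, TRUE), collapse = "")))
    map3 <- mapToReference(m3, "ref")
    expect_equal(map3$colToRes, cumsum(ch != "-"))
    expect_equal(map3$resToCol, which(ch != "-"))
  }
})

test_that("motif and residue conservation match hand counts", {
  rows <- c(NisCref = "AACHGAWCYGAA",
            s2     = "AACHGAWCYGAA",
            s3     = "AACHGAWCYGAA",
            s4     = "AAAHGAWCYGAA")  # CHG broken in one of four rows
  m <- toyMsa(rows)
  defs <- motifDefinition(c("CHG", "WCYG"), start = c(3L, 7L))
  tab <- motifConservation(m, defs, "NisCref")
  expect_equal(tab$percent_conserved[tab$name == "CHG"], 75)
  expect_equal(tab$percent_conserved[tab$name == "WCYG"], 100)
  # 9/10 rows with L at one column -> 90%
  rows2 <- c(ref = "ALG", paste0("r", 1:9))
  rows2[2:10] <- c(rep("ALG", 8), "AMG")
  names(rows2) <- c("ref", paste0("r", 1:9))
  m2 <- toyMsa(rows2)
  tab2 <- residueConservation(m2, positions = 2L, referenceId = "ref")
  expect_equal(tab2$percent_conserved, 90)
  expect_equal(tab2$name, "L2")
  # an all-wildcard pattern is always conserved
  tabx <- motifConservation(m, motifDefinition("xxx", 4L), "NisCref")
  expect_equal(tabx$percent_conserved, 100)
  # identical MSA: every position 100%
  m3 <- toyMsa(c(a = "MKCY", b = "MKCY", ref = "MKCY"))
  t3 <- residueConservation(m3, 1:4, "ref")
  expect_true(all(t3$percent_conserved == 100))
})

test_that("adding a motif-bearing row never lowers its conservation", {
  rows <- c(ref = "AACHGA", s2 = "AACHGA", s3 = "AAAHGA")
  defs <- motifDefinition("CHG", 3L)
  p0 <- motifConservation(toyMsa(rows), defs, "ref")$percent_conserved
  p1 <- motifConservation(toyMsa(c(rows, s4 = "AACHGA")), defs,
                          "ref")$percent_conserved
  expect_gte(p1, p0)
})

test_that("partial-motif breakdown reports per-letter conservation", {
  rows <- c(ref = "PAAARAANV",
            s2  = "PAAAKAANV",   # lacks the R
            s3  = "PAAARAAQV",   # lacks the N
            s4  = "PAAARAANV")
  m <- toyMsa(rows)
  tab <- motifConservation(m, motifDefinition("PxxxRxxNV", 1L), "ref",
                           breakdown = TRUE)
  full <- tab$percent_conserved[tab$name == "PxxxRxxNV"]
  expect_equal(full, 50)
  expect_equal(tab$percent_conserved[tab$name == "PxxxRxxNV:P1"], 100)
  expect_equal(tab$percent_conserved[tab$name == "PxxxRxxNV:R5"], 75)
  expect_equal(tab$percent_conserved[tab$name == "PxxxRxxNV:N8"], 75)
})

test_that("positions outside the reference are rejected", {
  m <- toyMsa(c(ref = "ACDEF", s2 = "ACDEF"))
  expect_error(motifConservation(m, motifDefinition("CHG", 4L), "ref"),
               "outside")
})

test_that("the builtin aligner matches the pairwise DP oracle and ungaps cleanly", {
  # identical sequences: gap-free alignment
  m <- buildMsa(Biostrings::AAStringSet(c(a = "MKCYLL", b = "MKCYLL")))
  expect_equal(ncol(m), 6L)
  expect_false(any(lantimine:::msaMatrix(m) == "-"))
  # textbook single-gap case
  m2 <- buildMsa(Biostrings::AAStringSet(c(a = "ACDEFG", b = "ACEFG")))
  mat <- lantimine:::msaMatrix(m2)
  expect_equal(ncol(m2), 6L)
  expect_equal(sum(mat == "-"), 1L)
  expect_equal(sum(mat["a", ] == mat["b", ]), 5L)
  # pairwise score equals the independent affine-gap DP (Biostrings)
  sc <- scoringScheme()
  spScore <- function(m) {
    mat <- lantimine:::msaMatrix(m)
    a <- mat[1, ]; b <- mat[2, ]
    s <- 0
    inGapA <- FALSE; inGapB <- FALSE
    for (k in seq_along(a)) {
      if (a[k] == "-") {
        s <- s - (if (inGapA) sc@gapExtend else sc@gapOpen + sc@gapExtend)
        inGapA <- TRUE; inGapB <- FALSE
      } else if (b[k] == "-") {
        s <- s - (if (inGapB) sc@gapExtend else sc@gapOpen + sc@gapExtend)
        inGapB <- TRUE; inGapA <- FALSE
      } else {
        s <- s + sc@matrix[a[k], b[k]]
        inGapA <- FALSE; inGapB <- FALSE
      }
    }
    s
  }
  set.seed(37)
  for (rep in 1:6) {
    x <- randProt(sample(30:80, 1))
    y <- randProt(sample(30:80, 1))
    m3 <- buildMsa(Biostrings::AAStringSet(c(x = x, y = y)))
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y),
      substitutionMatrix = sc@matrix, gapOpening = sc@gapOpen,
      gapExtension = sc@gapExtend, type = "global")
    expect_equal(spScore(m3), BiocGenerics::score(oracle))
    expect_equal(ungapRow(m3, "x"), x)
    expect_equal(ungapRow(m3, "y"), y)
  }
  # duplicate ids are rejected
  expect_error(buildMsa(Biostrings::AAStringSet(c(a = "MK", a = "MK"))),
               "duplicate")
})

test_that("multi-sequence alignments keep every input recoverable by ungapping", {
  set.seed(41)
  lib <- templateLibrary()
  seqs <- vapply(1:5, function(i)
    mutateProtein(as.character(lib$lanC[[1]]), 75,
                  protect = lib$protected$LanC_template), "")
  names(seqs) <- paste0("v", 1:5)
  m <- buildMsa(Biostrings::AAStringSet(seqs))
  for (id in names(seqs)) expect_equal(ungapRow(m, id), seqs[[id]])
  # the protected cyclase motifs stay perfectly conserved in the family
  msa <- buildMsa(Biostrings::AAStringSet(
    c(setNames(as.character(lib$lanC[[1]]), "LanC_template"), seqs)))
  tab <- motifConservation(msa, niscMotifs(), "LanC_template")
  expect_true(all(tab$percent_conserved == 100))
})
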