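test_that("six-frame scan finds simple ORFs on both strands", {
  # 25 codons + stop in frame +1
  pep <- "MKKAAAAAAAAAAKKKKKAAAAAAV"
  cds <- paste0("ATG", paste(vapply(strsplit(pep, "")[[1]][-1],
    function(a) lantimine:::CODON_TABLE[[a]][1], ""), collapse = ""), "TAA")
  dna <- paste0("CC", cds, "GG")
  o <- sixFrameOrfs(dna, minAA = 20L, maxAA = 120L)
  expect_equal(nrow(o), 1L)
  expect_equal(o$peptide, pep)
  expect_equal(o$strand, 1L)
  expect_equal(c(o$start, o$end), c(2L, 2L + nchar(cds)))
  # reverse complement: same peptide, minus strand, mirrored coordinates
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  o2 <- sixFrameOrfs(rc, minAA = 20L, maxAA = 120L)
  expect_equal(o2$peptide, pep)
  expect_equal(o2$strand, -1L)
  expect_equal(c(o2$start, o2$end), c(nchar(dna) - o$end, nchar(dna) - o$start))
  # too-short input
  expect_equal(nrow(sixFrameOrfs("ATGAAATAA", minAA = 10L, maxAA = 50L)), 0L)
})

test_that("six-frame scan equals the position-by-position brute-force oracle", {
  set.seed(17)
  for (rep in 1:15) {
    dna <- randDna(1500)
    got <- sixFrameOrfs(dna, minAA = 15L, maxAA = 200L)
    want <- bruteOrfs(dna, minAA = 15L, maxAA = 200L)
    gotM <- if (nrow(got)) cbind(got$start, got$end, got$strand) else NULL
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unname(gotM), unname(want))
    }
  }
})

test_that("leader/propeptide split behaves on reference, uniform and designed peptides", {
  # nisin A: annotated leader is 23 residues; expect the split nearby.
  sp <- splitLeader(NISA)
  expect_gte(sp$split_index, 18L)
  expect_lte(sp$split_index, 28L)
  # independent oracle: exhaustive scan over the same allowed window
  ch <- strsplit(NISA, "")[[1]]
  L <- length(ch)
  win <- seq.int(max(6L, floor(0.25 * L)), min(L - 10L, ceiling(0.75 * L)))
  dens <- vapply(win, function(i) {
    mean(ch[(i + 1):L] %in% c("S", "T", "C")) -
      mean(ch[1:i] %in% c("S", "T", "C"))
  }, numeric(1))
  expect_equal(sp$split_index, win[which.max(dens)])
  expect_equal(sp$skew, max(dens))
  # uniform composition: tie-break to the first allowed index
  expect_equal(splitLeader(strrep("A", 60))$split_index, 15L)
  # designed: 25 aa without S/T/C then 35 aa starting S/T/C-rich
  design <- paste0(strrep("ALKGF", 5), "STC", strrep("SAGKC", 6), "AA")
  expect_equal(splitLeader(design)$split_index, 25L)
})

test_that("the precursor filter accepts known type 1 precursors and rejects junk", {
  expect_false(scoreLana(randProt(500))$passes)          # far too long
  expect_false(scoreLana(strrep("A", 60))$passes)        # no S/T/C at all
  s <- scoreLana(NISA)
  expect_true(s$passes)
  expect_gte(s$cys_count, 1L)
  expect_true(all(c("leaderLeu", "CxxC") %in% s$leader_motif_hits))
  # gallidermin carries the canonical leader DLD box
  lib0 <- templateLibrary()
  expect_true("DLD" %in%
                scoreLana(as.character(lib0$lanA[["GdmA"]]))$leader_motif_hits)
  # other packaged precursors: nisin, subtilin, epidermin, gallidermin
  lib <- templateLibrary()
  for (id in c("NisA", "SpaS", "EpiA", "GdmA"))
    expect_true(scoreLana(as.character(lib$lanA[[id]]))$passes, label = id)
})

test_that("substituting a propeptide residue with Cys never lowers the composite", {
  set.seed(29)
  for (rep in 1:30) {
    p <- if (rep %% 2) mutateProtein(NISA, sample(70:95, 1)) else
      randProt(sample(40:80, 1))
    s0 <- scoreLana(p)
    ch <- strsplit(p, "")[[1]]
    # positions beyond 3/4 of the length lie in the propeptide for every
    # admissible split
    idx <- which(seq_along(ch) > ceiling(0.75 * length(ch)) &
                   !ch %in% c("S", "T", "C"))
    if (!length(idx)) next
    ch[sample(idx, 1)] <- "C"
    s1 <- scoreLana(paste(ch, collapse = ""))
    expect_gte(s1$composite, s0$composite - 1e-9)
  }
})

test_that("planted precursors pass and random decoys stay under 5% false passes", {
  lib <- templateLibrary()
  tpl <- as.character(lib$lanAPlant[[1]])
  expect_true(scoreLana(tpl)$passes)
  set.seed(97)
  planted <- replicate(100, mutateProtein(tpl, 75,
                                          protect = lib$protected$LanA_template))
  expect_true(all(vapply(planted, function(p) scoreLana(p)$passes,
                         logical(1))))
  decoys <- replicate(200, randProt(nchar(tpl)))
  fp <- mean(vapply(decoys, function(p) scoreLana(p)$passes, logical(1)))
  expect_lte(fp, 0.05)
})

test_that("candidate search distinguishes annotated and intergenic provenance", {
  gen <- generateGenome(genomeSpec(seed = 61, lengthNt = 90000,
                                   nComplete = 1, decoyGeneCount = 1))
  g <- gen$genome
  el <- gen$truth$elements
  anchorTags <- el$locus_tag[el$role %in% c("LanB", "LanC")]
  anchors <- S4Vectors::DataFrame(locus_tag = anchorTags,
                                  role_hypothesis = c("LanB", "LanC"))
  cand <- findLanaCandidates(g, anchors)
  lanaTruth <- el[el$role == "LanA", ]
  expect_gte(nrow(cand), 1L)
  expect_equal(cand$provenance[1], "annotated")
  expect_equal(cand$id[1], lanaTruth$locus_tag)
  # unannotated intergenic precursor
  gen2 <- generateGenome(genomeSpec(seed = 62, lengthNt = 90000,
                                    nComplete = 1, intergenicLana = TRUE,
                                    decoyGeneCount = 0))
  el2 <- gen2$truth$elements
  expect_false(el2$annotated[el2$role == "LanA"])
  anchors2 <- S4Vectors::DataFrame(
    locus_tag = el2$locus_tag[el2$role %in% c("LanB", "LanC")],
    role_hypothesis = c("LanB", "LanC"))
  cand2 <- findLanaCandidates(gen2$genome, anchors2)
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$provenance, "intergenic")
  expect_equal(cand2$start, el2$start[el2$role == "LanA"])
  expect_equal(cand2$end, el2$end[el2$role == "LanA"])
  # no anchors -> nothing
  expect_equal(nrow(findLanaCandidates(g, NULL)), 0L)
})
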