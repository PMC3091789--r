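test_that("self-alignment gives 100% identity and a tiny E-value; order symmetric", {
  set.seed(5)
  for (rep in 1:5) {
    a <- randProt(sample(50:200, 1))
    r <- alignPair(a, a)
    expect_equal(r$identity_pct, 100)
    expect_lt(r$evalue, 1e-7)
    b <- randProt(sample(50:200, 1))
    ab <- alignPair(a, b)
    ba <- alignPair(b, a)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity_pct, ba$identity_pct)
  }
})

test_that("identity on substitution-only pairs equals the Hamming oracle", {
  set.seed(8)
  for (rep in 1:8) {
    L <- sample(80:250, 1)
    nsub <- sample(5:round(0.35 * L), 1)
    a <- randProt(L)
    ch <- strsplit(a, "")[[1]]
    pos <- sample(L, nsub)
    for (p in pos) ch[p] <- sample(setdiff(AA, ch[p]), 1)
    b <- paste(ch, collapse = "")
    hamming <- 100 * (L - nsub) / L
    r <- alignPair(a, b, mode = "global")
    expect_equal(r$identity_pct, hamming, tolerance = 1e-9)
    expect_equal(r$aligned_cols, L)
  }
  # textbook case: 100 aa, exactly 30 substitutions -> 70%
  a <- randProt(100)
  ch <- strsplit(a, "")[[1]]
  for (p in sample(100, 30)) ch[p] <- sample(setdiff(AA, ch[p]), 1)
  expect_equal(alignPair(a, paste(ch, collapse = ""),
                         mode = "global")$identity_pct, 70)
})

test_that("illegal residues are rejected by name", {
  expect_error(alignPair("MKTA", "MK9A"), "9")
  expect_error(alignPair("MKJA", "MKTA"), "J")
})

test_that("screenProteome applies exactly the E-value and identity thresholds", {
  set.seed(11)
  driver <- Biostrings::AAStringSet(c(drv = randProt(400)))
  planted <- mutateProtein(as.character(driver[[1]]), 40)
  prots <- c(planted, replicate(30, randProt(sample(100:400, 1))))
  names(prots) <- sprintf("P%02d", seq_along(prots))
  proteome <- Biostrings::AAStringSet(prots)
  S4Vectors::mcols(proteome) <- S4Vectors::DataFrame(
    genome = "TST00001", locus_tag = names(prots))
  cfg <- screenConfig()
  hits <- screenProteome(driver, proteome, cfg = cfg, role = "LanC")
  # oracle: exhaustive alignPair with the same database size
  db <- sum(Biostrings::width(proteome))
  keep <- vapply(seq_along(proteome), function(i) {
    r <- alignPair(as.character(driver[[1]]), as.character(proteome[[i]]),
                   databaseSizeAA = db)
    r$evalue <= cfg@evalueMax && r$identity_pct > cfg@identityMinPct
  }, logical(1))
  expect_setequal(hits$locus_tag, names(prots)[keep])
  expect_true("P01" %in% hits$locus_tag)       # the planted homolog
  expect_false(is.unsorted(hits$evalue))
  expect_equal(unique(hits$role_hypothesis), "LanC")
  # a proteome containing the driver itself reports it
  proteome2 <- c(proteome, driver)
  S4Vectors::mcols(proteome2) <- S4Vectors::DataFrame(
    genome = "TST00001", locus_tag = c(names(prots), "drv"))
  expect_true("drv" %in% screenProteome(driver, proteome2)$locus_tag)
  # identityMinPct = 100 allows at most exact duplicates
  expect_equal(nrow(screenProteome(driver, proteome,
                                   cfg = screenConfig(identityMinPct = 100))),
               0L)
})

test_that("relaxing either threshold never removes a hit", {
  set.seed(12)
  driver <- Biostrings::AAStringSet(c(drv = randProt(300)))
  prots <- c(mutateProtein(as.character(driver[[1]]), 45),
             mutateProtein(as.character(driver[[1]]), 30),
             replicate(10, randProt(150)))
  names(prots) <- sprintf("Q%02d", seq_along(prots))
  proteome <- Biostrings::AAStringSet(prots)
  base <- screenProteome(driver, proteome, cfg = screenConfig())
  looserE <- screenProteome(driver, proteome,
                            cfg = screenConfig(evalueMax = 1e-3))
  looserI <- screenProteome(driver, proteome,
                            cfg = screenConfig(identityMinPct = 10))
  expect_true(all(base$target_id %in% looserE$target_id))
  expect_true(all(base$target_id %in% looserI$target_id))
})

test_that("iterative expansion reaches two-step homologs in round 2", {
  set.seed(23)
  lib <- templateLibrary()
  A <- randProt(300)
  B <- mutateProtein(A, 35)
  C <- mutateProtein(B, 35)
  # fixture validity: A finds B but not C directly
  cfg <- screenConfig(databaseSizeAA = 1000)
  rAB <- alignPair(A, B, databaseSizeAA = 1000)
  rAC <- alignPair(A, C, databaseSizeAA = 1000)
  expect_gt(rAB$identity_pct, 20)
  expect_lt(rAB$evalue, 1e-7)
  expect_false(rAC$evalue <= 1e-7 && rAC$identity_pct > 20)
  # plant B and C in two synthetic genomes as annotated CDS
  mkGenome <- function(accn, prot) {
    cds <- paste0("ATG", paste(vapply(strsplit(prot, "")[[1]][-1],
      function(a) lantimine:::CODON_TABLE[[a]][1], ""), collapse = ""), "TAA")
    GenomeRecord(accn, paste0(randDna(50), cds, randDna(50)),
                 S4Vectors::DataFrame(locus_tag = paste0(accn, "_1"),
                                      start = 50L,
                                      end = 50L + nchar(cds),
                                      strand = 1L, translation = prot,
                                      product = NA_character_))
  }
  genomes <- list(mkGenome("GENB0001", B), mkGenome("GENC0001", C))
  seeds <- Biostrings::AAStringSet(c(seedA = A))
  S4Vectors::mcols(seeds) <- S4Vectors::DataFrame(role = "LanC")
  r1 <- iterativeExpand(seeds, genomes, cfg = cfg, maxRounds = 1L)
  r3 <- iterativeExpand(seeds, genomes, cfg = cfg, maxRounds = 4L)
  expect_false("GENC0001_1" %in% r1$hits$locus_tag)
  expect_true("GENC0001_1" %in% r3$hits$locus_tag)
  expect_equal(r3$hits$round[r3$hits$locus_tag == "GENC0001_1"], 2L)
  # the hit set grows monotonically with rounds
  expect_true(all(paste(r1$hits$genome, r1$hits$locus_tag) %in%
                    paste(r3$hits$genome, r3$hits$locus_tag)))
  # fixed point: re-running from the full set adds nothing
  expect_lte(r3$roundsUsed, 3L)
})
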