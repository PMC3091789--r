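# Synthetic annotated genomes with planted lantibiotic clusters and full
# ground truth: the test bed for every pipeline stage.

#' Specification for a synthetic genome
#'
#' @param seed integer seed; the whole genome derives from it
#'   deterministically.
#' @param lengthNt total genome length (background is padded to reach it);
#'   an error states the minimum if too short.
#' @param nComplete,nNoLana,nOrphans planted cluster counts: complete
#'   (lanA+lanB+lanC+one accessory), lanA-less (lanB+lanC), and orphan
#'   (single lanB or lanC) loci.
#' @param intergenicLana if `TRUE`, the first complete cluster's lanA is
#'   written into the DNA without a CDS feature (unannotated).
#' @param frameshiftLanb if `TRUE`, the last complete cluster's lanB is
#'   split into two adjacent CDS (an 80-aa N-terminal part and the
#'   remainder), mimicking a frameshifted dehydratase gene.
#' @param decoyGeneCount unrelated random protein genes planted in the
#'   background.
#' @param mutationRate per-family substitution fraction in `[0, 0.8)`;
#'   planted proteins are mutated to `100 * (1 - mutationRate)` percent
#'   identity with functional residues protected.
#' @return validated list of class `GenomeSpec`.
#' @export
genomeSpec <- function(seed = 1L, lengthNt = 100000L, nComplete = 1L,
                       nNoLana = 0L, nOrphans = 0L, intergenicLana = FALSE,
                       frameshiftLanb = FALSE, decoyGeneCount = 3L,
                       mutationRate = 0) {
  stopifnot(nComplete >= 0L, nNoLana >= 0L, nOrphans >= 0L,
            decoyGeneCount >= 0L, mutationRate >= 0, mutationRate < 0.8)
  if (intergenicLana && nComplete < 1L)
    stop("intergenicLana requires at least one complete cluster")
  if (frameshiftLanb && nComplete < 1L)
    stop("frameshiftLanb requires at least one complete cluster")
  structure(list(seed = as.integer(seed), lengthNt = as.integer(lengthNt),
                 nComplete = as.integer(nComplete),
                 nNoLana = as.integer(nNoLana),
                 nOrphans = as.integer(nOrphans),
                 intergenicLana = intergenicLana,
                 frameshiftLanb = frameshiftLanb,
                 decoyGeneCount = as.integer(decoyGeneCount),
                 mutationRate = mutationRate),
            class = "GenomeSpec")
}

#' Mutate a protein to a target percent identity
#'
#' Substitutes `round(L * (1 - target/100))` positions chosen uniformly at
#' random (outside `protect`), replacing each residue by a different amino
#' acid drawn with BLOSUM62-weighted probabilities. Substitution-only, so
#' the Hamming identity to the original equals the target up to rounding.
#'
#' @param seq protein (character/AAString).
#' @param targetIdentityPct in `[20, 100]`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param protect positions never mutated (e.g. motif anchors).
#' @return mutated protein (character).
#' @export
mutateProtein <- function(seq, targetIdentityPct, seed = NULL,
                          protect = integer()) {
  stopifnot(targetIdentityPct >= 20, targetIdentityPct <= 100)
  run <- function() {
    ch <- aaChars(seq)
    L <- length(ch)
    nsub <- round(L * (1 - targetIdentityPct / 100))
    if (nsub == 0L) return(paste(ch, collapse = ""))
    eligible <- setdiff(seq_len(L), protect)
    if (nsub > length(eligible))
      stop("target identity unreachable under protection: need ", nsub,
           " substitutions but only ", length(eligible),
           " positions are mutable")
    pos <- sample(eligible, nsub)
    B <- scoringScheme()@matrix[AA20, AA20]
    for (p in pos) {
      orig <- ch[p]
      w <- exp(B[orig, ] / 2)
      w[orig] <- 0
      ch[p] <- sample(AA20, 1L, prob = w)
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else withLocalSeed(seed, run())
}

# uniform-synonymous-codon encoding; the encoded CDS includes a stop codon.
CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

encodeProtein <- function(aa) {
  ch <- aaChars(aa)
  codons <- vapply(seq_along(ch), function(i) {
    opts <- CODON_TABLE[[ch[i]]]
    # the first codon must not be an alternative start unless it encodes
    # Met, or re-translation would force the residue to M
    if (i == 1L && ch[i] != "M") opts <- setdiff(opts, BACTERIAL_STARTS)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         STOP_CODONS[sample.int(3L, 1L)])
}

# "stop wall": carries a stop codon in all three frames and is its own
# reverse complement, so it also stops all three minus-strand frames.
# Flanking every background segment with it confines stop-free runs to one
# segment, preventing open reading frames across segment junctions.
STOP_WALL <- "TTAATTAATTAA"

# random background DNA (GC ~0.5) in which every open reading frame of at
# least `minAA` codons is disrupted (in all six frames) by writing a stop
# codon at a random internal position, iterating to convergence; the
# randomized edits avoid the create/destroy cycles a fixed edit position
# can fall into. Keeps spurious precursor candidates out of intergenic DNA.
makeBackground <- function(n, minAA = 12L) {
  if (n <= 0L) return("")
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
             collapse = "")
  w <- nchar(STOP_WALL)
  s <- paste0(STOP_WALL, s, STOP_WALL)
  if (n >= 3L * minAA) {
    # suppress on the walled sequence (so reading frames ending in the
    # closing wall are seen), but only ever edit interior bases
    for (iter in 1:200) {
      orfs <- fastOrfScan(s, minAA = minAA)
      if (length(orfs$start) == 0L) break
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      for (k in seq_along(orfs$start)) {
        st <- orfs$start[k]; en <- orfs$end[k]
        ncod <- (en - st) %/% 3L
        # candidate codons: internal, and fully inside the random interior
        ci <- seq.int(2L, ncod - 1L)
        ok <- (st + 3L * (ci - 1L)) >= w & (st + 3L * ci) <= w + n
        ci <- ci[ok]
        if (!length(ci)) next
        mid <- st + 3L * (ci[sample.int(length(ci), 1L)] - 1L)
        sc <- strsplit(sample(STOP_CODONS, 1L), "", fixed = TRUE)[[1L]]
        if (orfs$strand[k] < 0L) sc <- rev(chartr("ACGT", "TGCA", sc))
        ch[(mid + 1L):(mid + 3L)] <- sc
      }
      s <- paste(ch, collapse = "")
    }
  }
  s
}

# one planted gene: list(seq=..., protein=..., role=..., annotated=...)
plantGene <- function(role, protein, annotated = TRUE, template = role) {
  list(role = role, protein = protein, seq = encodeProtein(protein),
       annotated = annotated, template = template)
}

mutateTemplate <- function(lib, templateId, set, idPct) {
  tpl <- as.character(set[[1L]])
  if (idPct >= 100) return(tpl)
  mutateProtein(tpl, idPct, protect = lib$protected[[templateId]])
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Plants complete (lanA/lanB/lanC + accessory), lanA-less and orphan
#' lantibiotic loci on random strands, with intra-cluster gaps of
#' 50-500 nt, clusters separated by at least three clustering windows of
#' ORF-suppressed background, plus unrelated decoy genes. Optionally one
#' lanA is left unannotated in intergenic DNA and one lanB is split across
#' two CDS by a simulated frameshift. Output is byte-deterministic in the
#' seed.
#'
#' @param spec a [genomeSpec()].
#' @param lib a [templateLibrary()] (built if missing).
#' @return list: `genome` (a [GenomeRecord-class]), `truth` (list of
#'   DataFrames `elements` and `clusters`).
#' @export
generateGenome <- function(spec, lib = templateLibrary()) {
  stopifnot(inherits(spec, "GenomeSpec"))
  withLocalSeed(spec$seed, generateGenomeImpl(spec, lib))
}

generateGenomeImpl <- function(spec, lib) {
  idPct <- 100 * (1 - spec$mutationRate)
  sep <- 31000L  # >= 3 x default clustering window
  gap <- function() sample(50:500, 1L)

  # build the planted units -------------------------------------------------
  units <- list()   # each: list(type, genes=list of plantGene, strand)
  accFams <- c("LanT", "OMT")
  for (i in seq_len(spec$nComplete)) {
    genes <- list(
      plantGene("LanA", mutateTemplate(lib, "LanA_template", lib$lanAPlant,
                                       idPct),
                annotated = !(spec$intergenicLana && i == 1L),
                template = "LanA_template"),
      plantGene("LanB", mutateTemplate(lib, "LanB_template", lib$lanB,
                                       idPct), template = "LanB_template"),
      plantGene("LanC", mutateTemplate(lib, "LanC_template", lib$lanC,
                                       idPct), template = "LanC_template"),
      plantGene(accFams[(i - 1L) %% 2L + 1L],
                mutateProtein(as.character(
                  lib$accessory[[accFams[(i - 1L) %% 2L + 1L]]]), max(idPct, 85)),
                template = accFams[(i - 1L) %% 2L + 1L]))
    units[[length(units) + 1L]] <- list(
      type = "COMPLETE", genes = genes,
      strand = sample(c(1L, -1L), 1L),
      frameshift = spec$frameshiftLanb && i == spec$nComplete)
  }
  for (i in seq_len(spec$nNoLana)) {
    genes <- list(
      plantGene("LanB", mutateTemplate(lib, "LanB_template", lib$lanB,
                                       idPct), template = "LanB_template"),
      plantGene("LanC", mutateTemplate(lib, "LanC_template", lib$lanC,
                                       idPct), template = "LanC_template"))
    units[[length(units) + 1L]] <- list(type = "NO_LANA", genes = genes,
                                        strand = sample(c(1L, -1L), 1L),
                                        frameshift = FALSE)
  }
  orphanRoles <- rep(c("LanC", "LanB"), length.out = spec$nOrphans)
  for (i in seq_len(spec$nOrphans)) {
    role <- orphanRoles[i]
    set <- if (role == "LanB") lib$lanB else lib$lanC
    genes <- list(plantGene(role, mutateTemplate(
      lib, paste0(role, "_template"), set, idPct),
      template = paste0(role, "_template")))
    units[[length(units) + 1L]] <- list(type = "ORPHAN", genes = genes,
                                        strand = sample(c(1L, -1L), 1L),
                                        frameshift = FALSE)
  }

  # assemble each unit into a + strand segment, then flip if needed --------
  segs <- list()       # character segments of the genome
  elements <- list()   # absolute-coordinate truth rows (filled later)
  clustersTruth <- list()
  pos <- 0L
  pushSeg <- function(s) {
    segs[[length(segs) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  pushSeg(makeBackground(1500L))

  clusterId <- 0L
  for (u in units) {
    clusterId <- clusterId + 1L
    segSeq <- character()
    segFeats <- list()  # within-segment rows (0-based, + strand build)
    at <- 0L
    addPiece <- function(s) {
      segSeq[[length(segSeq) + 1L]] <<- s
      at <<- at + nchar(s)
    }
    addGene <- function(gene, frameshift = FALSE) {
      if (!gene$annotated) {
        # in-frame stop immediately upstream pins the ORF start
        addPiece("TAA")
        s0 <- at
        addPiece(gene$seq)
        segFeats[[length(segFeats) + 1L]] <<- list(
          role = gene$role, start = s0, end = at, annotated = FALSE,
          protein = gene$protein, template = gene$template)
        return(invisible())
      }
      if (frameshift) {
        ch <- aaChars(gene$protein)
        pa <- paste(ch[1:80], collapse = "")
        pb <- paste0("M", paste(ch[81:length(ch)], collapse = ""))
        s0 <- at
        addPiece(encodeProtein(pa))
        segFeats[[length(segFeats) + 1L]] <<- list(
          role = gene$role, start = s0, end = at, annotated = TRUE,
          protein = pa, template = gene$template, part = "a")
        addPiece(makeBackground(20L))
        s1 <- at
        addPiece(encodeProtein(pb))
        segFeats[[length(segFeats) + 1L]] <<- list(
          role = gene$role, start = s1, end = at, annotated = TRUE,
          protein = pb, template = gene$template, part = "b")
        return(invisible())
      }
      s0 <- at
      addPiece(gene$seq)
      segFeats[[length(segFeats) + 1L]] <<- list(
        role = gene$role, start = s0, end = at, annotated = TRUE,
        protein = gene$protein, template = gene$template)
    }
    for (gi in seq_along(u$genes)) {
      g <- u$genes[[gi]]
      addGene(g, frameshift = u$frameshift && g$role == "LanB")
      if (gi < length(u$genes)) addPiece(makeBackground(gap()))
    }
    seg <- paste(segSeq, collapse = "")
    segLen <- nchar(seg)
    if (u$strand < 0L) {
      seg <- as.character(reverseComplement(DNAString(seg)))
      segFeats <- lapply(segFeats, function(fe) {
        s <- segLen - fe$end; e <- segLen - fe$start
        fe$start <- s; fe$end <- e
        fe
      })
    }
    for (fe in segFeats) {
      elements[[length(elements) + 1L]] <- c(fe, list(
        abs_start = pos + fe$start, abs_end = pos + fe$end,
        strand = u$strand, cluster_id = clusterId))
    }
    clustersTruth[[length(clustersTruth) + 1L]] <- list(
      cluster_id = clusterId, classification = u$type,
      start = pos, end = pos + segLen)
    pushSeg(seg)
    pushSeg(makeBackground(sep))
  }

  for (i in seq_len(spec$decoyGeneCount)) {
    prot <- randomProtein(sample(80:350, 1L))
    strand <- sample(c(1L, -1L), 1L)
    cds <- encodeProtein(prot)
    if (strand < 0L) {
      cds <- as.character(reverseComplement(DNAString(cds)))
      prot <- prot  # translation unchanged
    }
    elements[[length(elements) + 1L]] <- list(
      role = "decoy", start = 0L, end = nchar(cds), annotated = TRUE,
      protein = prot, template = "decoy",
      abs_start = pos, abs_end = pos + nchar(cds), strand = strand,
      cluster_id = NA_integer_)
    pushSeg(cds)
    pushSeg(makeBackground(1500L))
  }

  needed <- pos
  if (spec$lengthNt < needed)
    stop("genome too short for requested content; minimum length is ",
         needed, " nt")
  if (spec$lengthNt > needed) pushSeg(makeBackground(spec$lengthNt - needed))
  dna <- paste(segs, collapse = "")

  # features & locus tags in positional order ------------------------------
  ord <- order(vapply(elements, function(e) e$abs_start, numeric(1)))
  elements <- elements[ord]
  tag <- 0L
  rows <- list()
  featRows <- list()
  for (e in elements) {
    lt <- NA_character_
    if (e$annotated) {
      tag <- tag + 1L
      lt <- sprintf("SYN_%04d", tag)
      featRows[[length(featRows) + 1L]] <- DataFrame(
        locus_tag = lt, start = e$abs_start, end = e$abs_end,
        strand = e$strand, translation = e$protein,
        product = if (e$role == "decoy") "hypothetical protein"
                  else paste("putative", e$role, "family protein"))
    }
    rows[[length(rows) + 1L]] <- DataFrame(
      role = e$role, start = e$abs_start, end = e$abs_end,
      strand = e$strand, locus_tag = lt,
      cluster_id = e$cluster_id, template = e$template,
      annotated = e$annotated,
      part = if (!is.null(e$part)) e$part else NA_character_,
      protein = e$protein)
  }
  feats <- if (length(featRows)) do.call(rbind, featRows) else NULL
  acc <- sprintf("SYNGEN%05d", spec$seed %% 100000L)
  genome <- GenomeRecord(acc, dna, feats)
  elementsDF <- do.call(rbind, rows)
  elementsDF$genome <- acc
  clustersDF <- do.call(rbind, lapply(clustersTruth, function(ct)
    DataFrame(cluster_id = ct$cluster_id,
              classification = ct$classification,
              start = ct$start, end = ct$end,
              genome = acc)))
  if (is.null(clustersDF))
    clustersDF <- DataFrame(cluster_id = integer(),
                            classification = character(),
                            start = integer(), end = integer(),
                            genome = character())
  list(genome = genome,
       truth = list(elements = elementsDF, clusters = clustersDF))
}

#' Write a synthetic genome bundle to disk
#'
#' GenBank flat file, protein FASTA of the annotated proteome, and the
#' ground-truth tables as TSV.
#'
#' @param gen result of [generateGenome()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeGenomeBundle <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- accession(gen$genome)
  writeGenBank(gen$genome, file.path(dir, paste0(acc, ".gbk")))
  prot <- extractProteome(gen$genome)
  writeXStringSet(prot, file.path(dir, paste0(acc, ".faa")))
  el <- gen$truth$elements
  write.table(as.data.frame(el[, setdiff(colnames(el), "protein")]),
              file.path(dir, paste0(acc, "_truth_elements.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(gen$truth$clusters),
              file.path(dir, paste0(acc, "_truth_clusters.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
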