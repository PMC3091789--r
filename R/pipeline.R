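# End-to-end orchestration: screen -> frameshift merge -> LanA discovery ->
# cluster assembly -> accessory annotation -> report, with optional
# conservation tables and trees per role.

#' Pipeline configuration
#'
#' @param genomes list of [GenomeRecord-class] objects, or paths to GenBank
#'   files (each may hold several contigs).
#' @param drivers driver proteins ([Biostrings::AAStringSet] with `mcols`
#'   column `role`); default [defaultDrivers()].
#' @param scheme a [ScoringScheme-class].
#' @param screen a [ScreenConfig-class].
#' @param lana a [LanaConfig-class].
#' @param windowNt clustering / LanA search window (default 10000).
#' @param maxRounds iterative-expansion rounds (default 1: seed drivers
#'   only).
#' @param refFamilies accessory reference families (named AAStringSet);
#'   default: the template library's.
#' @param outDir optional output directory for TSV/FASTA/Newick artefacts.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(genomes, drivers = NULL, scheme = scoringScheme(),
                           screen = screenConfig(), lana = lanaConfig(),
                           windowNt = 10000L, maxRounds = 1L,
                           refFamilies = NULL, outDir = NULL) {
  if (!length(genomes)) stop("empty genome set")
  lib <- templateLibrary()
  if (is.null(drivers)) drivers <- defaultDrivers(lib)
  if (is.null(refFamilies)) refFamilies <- lib$accessory
  structure(list(genomes = genomes, drivers = drivers, scheme = scheme,
                 screen = screen, lana = lana,
                 windowNt = as.integer(windowNt),
                 maxRounds = as.integer(maxRounds),
                 refFamilies = refFamilies, outDir = outDir),
            class = "PipelineConfig")
}

loadGenomes <- function(genomes) {
  out <- list()
  for (g in genomes) {
    if (is.character(g)) {
      r <- readGenBank(g)
      if (is(r, "GenomeRecord")) r <- list(r)
      out <- c(out, r)
    } else out <- c(out, list(g))
  }
  names(out) <- vapply(out, accession, character(1))
  out
}

#' Run the full mining pipeline
#'
#' For each genome: screen the annotated proteome with the drivers
#' (iteratively if `maxRounds > 1`), merge frameshift-split hits against
#' the matching driver, search annotated small CDS and intergenic
#' six-frame ORFs near LanB/LanC anchors for LanA candidates, assemble and
#' classify clusters, and annotate accessory genes. Deterministic given
#' inputs. When `outDir` is set, writes the member table
#' (`clusters.tsv`), per-role FASTA bundles, conservation tables and
#' Newick trees for roles with at least 3 members.
#'
#' @param cfg a [pipelineConfig()].
#' @return a [ScreenReport-class].
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  genomes <- loadGenomes(cfg$genomes)
  xp <- iterativeExpand(cfg$drivers, genomes, cfg$scheme, cfg$screen,
                         maxRounds = cfg$maxRounds)
  hits <- xp$hits
  refs <- list(LanB = cfg$drivers[[match("LanB", mcols(cfg$drivers)$role)]],
               LanC = cfg$drivers[[match("LanC", mcols(cfg$drivers)$role)]])
  refs <- lapply(refs, as.character)

  clusters <- list()
  rowsOut <- list()
  allLana <- list()
  merges <- list()
  for (acc in names(genomes)) {
    g <- genomes[[acc]]
    gHits <- hits[!is.na(hits$genome) & hits$genome == acc, , drop = FALSE]
    if (nrow(gHits) == 0L) next
    # fuse frameshift-split hits
    mg <- findFrameshiftMerges(g, gHits, refs, scheme = cfg$scheme)
    if (length(mg) && is.null(gHits$start)) {
      gHits$start <- NA_integer_
      gHits$end <- NA_integer_
      gHits$strand <- NA_integer_
    }
    for (m in mg) {
      partRows <- match(c(m$part_a, m$part_b), gHits$locus_tag)
      partRows <- partRows[!is.na(partRows)]
      keep <- gHits[partRows[1L], , drop = FALSE]
      keep$locus_tag <- paste(m$part_a, m$part_b, sep = "+")
      keep$target_id <- keep$locus_tag
      keep$start <- as.integer(m$start)
      keep$end <- as.integer(m$end)
      keep$strand <- as.integer(m$strand)
      gHits <- rbind(gHits[-partRows, , drop = FALSE], keep)
      merges[[length(merges) + 1L]] <- c(list(genome = acc), m)
    }
    anchors <- gHits[gHits$role_hypothesis %in% c("LanB", "LanC"), ,
                     drop = FALSE]
    lana <- findLanaCandidates(g, anchors, windowNt = cfg$windowNt,
                               cfg = cfg$lana)
    if (nrow(lana)) {
      lana$genome <- acc
      allLana[[length(allLana) + 1L]] <- lana
    }
    cl <- assembleClusters(gHits, lana, g, windowNt = cfg$windowNt)
    cl <- lapply(cl, annotateAccessory, g = g,
                 refFamilies = cfg$refFamilies, scheme = cfg$scheme,
                 cfg = cfg$screen)
    clusters <- c(clusters, cl)
  }

  rows <- list()
  for (ci in seq_along(clusters)) {
    cc <- clusters[[ci]]
    m <- members(cc)
    for (i in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- DataFrame(
        genome = cc@genome, cluster = ci,
        classification = classification(cc),
        id = m$id[i], role = m$role[i], start = m$start[i], end = m$end[i],
        strand = m$strand[i], identity_pct = m$identity_pct[i],
        evalue = m$evalue[i], provenance = m$provenance[i])
    }
  }
  rowsDF <- if (length(rows)) do.call(rbind, rows) else
    DataFrame(genome = character(), cluster = integer(),
              classification = character(), id = character(),
              role = character(), start = integer(), end = integer(),
              strand = integer(), identity_pct = numeric(),
              evalue = numeric(), provenance = character())
  cls <- vapply(clusters, classification, character(1))
  summary <- list(
    n_complete = sum(cls == "COMPLETE"),
    n_nolana = sum(cls == "NO_LANA"),
    n_orphan = sum(cls == "ORPHAN"),
    n_multi_lanc = sum(cls == "MULTI_LANC_NO_A"),
    n_clusters = length(clusters),
    n_hits = nrow(hits),
    n_merges = length(merges),
    rounds_used = xp$roundsUsed)
  report <- new("ScreenReport", rows = rowsDF, summary = summary,
             clusters = clusters)
  attr(report, "lana") <- if (length(allLana)) do.call(rbind, allLana) else NULL
  attr(report, "hits") <- hits
  attr(report, "merges") <- merges

  if (!is.null(cfg$outDir)) writePipelineOutputs(report, genomes, cfg)
  report
}

# collect per-role member peptides across the report's clusters
rolePeptides <- function(report, genomes, role) {
  out <- character()
  for (cc in report@clusters) {
    m <- members(cc)
    g <- genomes[[cc@genome]]
    f <- features(g)
    for (i in which(m$role == role)) {
      pep <- if (m$provenance[i] == "intergenic") {
        lana <- attr(report, "lana")
        lana$peptide[match(m$id[i], lana$id)]
      } else if (grepl("+", m$id[i], fixed = TRUE)) {
        parts <- strsplit(m$id[i], "+", fixed = TRUE)[[1L]]
        paste0(f$translation[match(parts, f$locus_tag)], collapse = "")
      } else f$translation[match(m$id[i], f$locus_tag)]
      if (!is.na(pep)) out[paste(cc@genome, m$id[i], sep = "|")] <- pep
    }
  }
  out
}

writePipelineOutputs <- function(report, genomes, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(reportRows(report)),
              file.path(cfg$outDir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lib <- templateLibrary()
  refSeq <- list(LanA = as.character(lib$lanAPlant[[1L]]),
                 LanB = as.character(lib$lanB[[1L]]),
                 LanC = as.character(lib$lanC[[1L]]))
  refName <- list(LanA = "LanA_template", LanB = "LanB_template",
                  LanC = "LanC_template")
  defs <- list(LanB = nisbMotifs(), LanC = niscMotifs())
  for (role in c("LanA", "LanB", "LanC")) {
    peps <- rolePeptides(report, genomes, role)
    if (!length(peps)) next
    set <- AAStringSet(peps)
    writeXStringSet(set, file.path(cfg$outDir, paste0(role, ".faa")))
    if (length(peps) >= 3L) {
      seqs <- c(stats::setNames(AAStringSet(refSeq[[role]]),
                                refName[[role]]), set)
      msa <- buildMsa(seqs, scheme = cfg$scheme)
      if (!is.null(defs[[role]])) {
        tab <- motifConservation(msa, defs[[role]], refName[[role]])
        writeConservationTable(tab, file.path(
          cfg$outDir, paste0(role, "_conservation.tsv")))
      }
      d <- distanceMatrix(msa)
      tree <- njTree(d)
      ape::write.tree(tree, file.path(cfg$outDir, paste0(role, ".nwk")))
    }
  }
  invisible(NULL)
}

#' Compare a screen report against generator ground truth
#'
#' Matches reported clusters to planted clusters by genomic overlap and
#' classification, and reports recovery statistics.
#'
#' @param report a [ScreenReport-class].
#' @param truths list of `truth` objects from [generateGenome()], named by
#'   genome accession (or unnamed; accessions are read from the truth
#'   tables).
#' @return list: `n_planted`, `n_reported`, `n_recovered` (planted
#'   clusters overlapped by a reported cluster of the same
#'   classification), `n_false` (reported clusters matching no planted
#'   cluster), `sensitivity`, `fdr`.
#' @export
compareToTruth <- function(report, truths) {
  planted <- do.call(rbind, lapply(truths, function(t) t$clusters))
  cls <- report@clusters
  nPlanted <- nrow(planted)
  recovered <- logical(nPlanted)
  usedBy <- rep(NA_integer_, length(cls))
  for (ci in seq_along(cls)) {
    cc <- cls[[ci]]
    sp <- clusterSpan(cc)
    for (pi in seq_len(nPlanted)) {
      if (planted$genome[pi] != cc@genome) next
      if (sp[1L] < planted$end[pi] && sp[2L] > planted$start[pi]) {
        usedBy[ci] <- pi
        if (classification(cc) == planted$classification[pi])
          recovered[pi] <- TRUE
      }
    }
  }
  nFalse <- sum(is.na(usedBy))
  list(n_planted = nPlanted, n_reported = length(cls),
       n_recovered = sum(recovered), n_false = nFalse,
       sensitivity = if (nPlanted) sum(recovered) / nPlanted else NA_real_,
       fdr = if (length(cls)) nFalse / length(cls) else 0)
}
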