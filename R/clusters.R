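# Cluster assembly and classification; frameshift-split LanB merging;
# accessory-gene annotation.

CLUSTER_ROLES <- c("LanA", "LanB", "LanC", "LanT", "LanP", "LanEFG",
                   "LanKR", "LanD", "OMT", "other")

#' Classify a gene cluster by its role content
#'
#' `COMPLETE` when the cluster holds at least one each of LanA, LanB and
#' LanC; `MULTI_LANC_NO_A` when it holds two or more LanC genes but no
#' structural peptide; `NO_LANA` when LanB and LanC are present without a
#' LanA; everything else is an `ORPHAN` (an isolated homolog with no
#' co-clustered lantibiotic-role partner).
#'
#' @param x a [GeneCluster-class] or a character vector of member roles.
#' @return classification label (character).
#' @export
classifyCluster <- function(x) {
  roles <- if (is(x, "GeneCluster")) members(x)$role else x
  nA <- sum(roles == "LanA")
  nB <- sum(roles == "LanB")
  nC <- sum(roles == "LanC")
  if (nA >= 1L && nB >= 1L && nC >= 1L) return("COMPLETE")
  if (nC >= 2L && nA == 0L) return("MULTI_LANC_NO_A")
  if (nB >= 1L && nC >= 1L && nA == 0L) return("NO_LANA")
  "ORPHAN"
}

#' Assemble hits and LanA candidates into gene clusters
#'
#' Single-linkage grouping on the genome axis: two elements belong to the
#' same cluster when their intervals lie within `windowNt` of each other.
#' Each cluster is classified with [classifyCluster()].
#'
#' @param hits DataFrame of LanB/LanC homolog hits on `g` (needs
#'   `locus_tag`, `role_hypothesis`, `identity_pct`, `evalue`; coordinates
#'   are looked up in `g`'s features, or taken from `start`/`end` columns
#'   when present).
#' @param lana DataFrame of LanA candidates from [findLanaCandidates()]
#'   (may be `NULL` or empty).
#' @param g the [GenomeRecord-class] the inputs refer to.
#' @param windowNt single-linkage joining distance (default 10000).
#' @return list of [GeneCluster-class], ordered by genomic start.
#' @export
assembleClusters <- function(hits, lana = NULL, g, windowNt = 10000L) {
  f <- features(g)
  rows <- list()
  if (!is.null(hits) && nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      if (!is.null(hits$start) && !is.na(hits$start[i])) {
        s <- hits$start[i]; e <- hits$end[i]
        str <- if (!is.null(hits$strand)) hits$strand[i] else NA_integer_
      } else {
        j <- match(hits$locus_tag[i], f$locus_tag)
        if (is.na(j)) next
        s <- f$start[j]; e <- f$end[j]; str <- f$strand[j]
      }
      rows[[length(rows) + 1L]] <- DataFrame(
        id = hits$locus_tag[i], role = hits$role_hypothesis[i],
        start = as.integer(s), end = as.integer(e),
        strand = as.integer(str),
        identity_pct = hits$identity_pct[i], evalue = hits$evalue[i],
        provenance = "annotated")
    }
  }
  if (!is.null(lana) && nrow(lana)) {
    for (i in seq_len(nrow(lana))) {
      rows[[length(rows) + 1L]] <- DataFrame(
        id = lana$id[i], role = "LanA",
        start = as.integer(lana$start[i]), end = as.integer(lana$end[i]),
        strand = as.integer(lana$strand[i]),
        identity_pct = NA_real_, evalue = NA_real_,
        provenance = lana$provenance[i])
    }
  }
  if (!length(rows)) return(list())
  m <- do.call(rbind, rows)
  m <- m[order(m$start, m$end, m$id), , drop = FALSE]
  # single-linkage chaining along the genome
  cl <- integer(nrow(m))
  cl[1L] <- 1L
  maxEnd <- m$end[1L]
  for (i in seq_len(nrow(m))[-1L]) {
    cl[i] <- if (m$start[i] - maxEnd <= windowNt) cl[i - 1L] else
      cl[i - 1L] + 1L
    maxEnd <- max(maxEnd, m$end[i])
  }
  lapply(split(seq_len(nrow(m)), cl), function(idx) {
    mm <- m[idx, , drop = FALSE]
    rownames(mm) <- NULL
    cc <- new("GeneCluster", genome = accession(g),
              span = c(min(mm$start), max(mm$end)),
              members = mm, classification = "ORPHAN")
    cc@classification <- classifyCluster(cc)
    cc
  })
}

#' Merge a frameshift-split gene pair against an intact reference
#'
#' Tests whether two adjacent same-strand CDS are the two halves of a
#' frameshift-split gene: the upstream part must align to the N-terminal
#' region of the reference and the downstream part to the C-terminal
#' region, with non-overlapping reference spans, combined reference
#' coverage of at least `minCoverage`, and a combined length within
#' 80-120% of the reference.
#'
#' @param partA,partB peptides (character/AAString) of the upstream and
#'   downstream CDS (in genome orientation for + strand; for - strand pass
#'   the biological N-terminal part as `partA`).
#' @param reference intact reference protein.
#' @param scheme a [ScoringScheme-class].
#' @param minCoverage combined reference-coverage threshold (default 0.7).
#' @return `NULL` if rejected, else a list with `merged_peptide`,
#'   `coverage_a`, `coverage_b`, `reference_span_a`, `reference_span_b`.
#' @export
mergeFrameshift <- function(partA, partB, reference,
                            scheme = scoringScheme(), minCoverage = 0.7) {
  refLen <- nchar(as.character(reference))
  a <- alignPair(as.character(partA), as.character(reference),
                 scheme = scheme, mode = "local")
  b <- alignPair(as.character(partB), as.character(reference),
                 scheme = scheme, mode = "local")
  spanA <- c(a$tstart, a$tend)
  spanB <- c(b$tstart, b$tend)
  if (spanA[1L] >= spanB[1L]) return(NULL)       # A must be N-terminal
  if (spanA[2L] >= spanB[1L]) return(NULL)       # non-overlapping spans
  covA <- (spanA[2L] - spanA[1L] + 1L) / refLen
  covB <- (spanB[2L] - spanB[1L] + 1L) / refLen
  if (covA + covB < minCoverage) return(NULL)
  merged <- paste0(as.character(partA), as.character(partB))
  if (nchar(merged) < 0.8 * refLen || nchar(merged) > 1.2 * refLen)
    return(NULL)
  list(merged_peptide = merged, coverage_a = covA, coverage_b = covB,
       reference_span_a = spanA, reference_span_b = spanB)
}

# Scan a genome for adjacent same-strand CDS pairs (gap <= maxGapNt) whose
# concatenation matches a reference; returns merge records used by the
# pipeline to fuse split LanB hits.
findFrameshiftMerges <- function(g, hits, references,
                                 scheme = scoringScheme(),
                                 maxGapNt = 100L) {
  f <- features(g)
  out <- list()
  if (nrow(f) < 2L || is.null(hits) || nrow(hits) == 0L) return(out)
  hitTags <- hits$locus_tag
  for (i in seq_len(nrow(f) - 1L)) {
    j <- i + 1L
    if (f$strand[i] != f$strand[j]) next
    gap <- f$start[j] - f$end[i]
    if (gap < 0L || gap > maxGapNt) next
    tags <- c(f$locus_tag[i], f$locus_tag[j])
    if (!any(tags %in% hitTags)) next
    role <- hits$role_hypothesis[match(tags, hits$locus_tag)]
    role <- role[!is.na(role)][1L]
    ref <- references[[role]]
    if (is.null(ref)) next
    # biological order: on - strand the downstream CDS is the N-terminus
    if (f$strand[i] > 0L) {
      pa <- f$translation[i]; pb <- f$translation[j]
      partTags <- tags
    } else {
      pa <- f$translation[j]; pb <- f$translation[i]
      partTags <- rev(tags)
    }
    mg <- mergeFrameshift(pa, pb, ref, scheme = scheme)
    if (is.null(mg)) next
    out[[length(out) + 1L]] <- c(
      list(part_a = partTags[1L], part_b = partTags[2L], role = role,
           start = f$start[i], end = f$end[j], strand = f$strand[i]), mg)
  }
  out
}

#' Annotate accessory genes within a cluster
#'
#' Screens every CDS inside the cluster span that has no assigned role
#' against a set of reference-family exemplars (transporter LanT, protease
#' LanP, immunity LanEFG, two-component LanKR, decarboxylase LanD,
#' O-methyltransferase) under the usual screen thresholds; each gene gets
#' the role of its best passing hit, else `"other"`. The search region is
#' the member span extended by `windowNt` on each side, since accessory
#' genes commonly flank the core biosynthetic genes.
#'
#' @param cluster a [GeneCluster-class].
#' @param g the [GenomeRecord-class].
#' @param refFamilies named [Biostrings::AAStringSet]; names are roles
#'   (`LanT`, `LanP`, `LanEFG`, `LanKR`, `LanD`, `OMT`), possibly repeated.
#' @param scheme a [ScoringScheme-class].
#' @param cfg a [ScreenConfig-class].
#' @param windowNt flank width searched beyond the member span.
#' @return the cluster with accessory members appended (classification is
#'   unchanged: accessory genes do not affect it).
#' @export
annotateAccessory <- function(cluster, g, refFamilies,
                              scheme = scoringScheme(),
                              cfg = screenConfig(), windowNt = 10000L) {
  f <- features(g)
  span <- clusterSpan(cluster)
  lo <- span[1L] - windowNt
  hi <- span[2L] + windowNt
  inside <- which(f$start < hi & f$end > lo)
  # member ids, including the halves of merged frameshift-split genes
  known <- unlist(strsplit(members(cluster)$id, "+", fixed = TRUE))
  newRows <- list()
  for (i in inside) {
    if (f$locus_tag[i] %in% known) next
    pep <- f$translation[i]
    if (is.na(pep) || !nzchar(pep)) next
    best <- NULL
    for (k in seq_along(refFamilies)) {
      r <- alignPair(as.character(refFamilies[[k]]), pep, scheme = scheme,
                     mode = "local", databaseSizeAA = sum(width(refFamilies)))
      if (r$evalue <= cfg@evalueMax && r$identity_pct > cfg@identityMinPct &&
          (is.null(best) || r$evalue < best$evalue)) {
        best <- r
        best$role <- names(refFamilies)[k]
      }
    }
    role <- if (!is.null(best)) best$role else "other"
    newRows[[length(newRows) + 1L]] <- DataFrame(
      id = f$locus_tag[i], role = role,
      start = f$start[i], end = f$end[i], strand = f$strand[i],
      identity_pct = if (!is.null(best)) best$identity_pct else NA_real_,
      evalue = if (!is.null(best)) best$evalue else NA_real_,
      provenance = "annotated")
  }
  if (length(newRows)) {
    mm <- rbind(members(cluster), do.call(rbind, newRows))
    mm <- mm[order(mm$start, mm$end), , drop = FALSE]
    rownames(mm) <- NULL
    cluster@members <- mm
    cluster@span <- c(min(mm$start), max(mm$end))
  }
  cluster
}
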