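# Driver-based protein homology screening with affine-gap alignment,
# BLAST-like E-values, and iterative driver expansion.

#' Construct a scoring scheme
#'
#' Defaults mirror blastp: BLOSUM62 with gap open 11 / extend 1 and the
#' published gapped Karlin-Altschul constants (lambda 0.267, K 0.041).
#'
#' @param matrix substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM250"`) or a symmetric numeric matrix.
#' @param gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   `gapOpen + L * gapExtend`.
#' @param lambda,K Karlin-Altschul parameters.
#' @return a [ScoringScheme-class].
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                          lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  new("ScoringScheme", matrix = matrix, gapOpen = gapOpen,
      gapExtend = gapExtend, lambda = lambda, K = K)
}

#' Construct screen thresholds
#'
#' @param evalueMax maximum E-value for a hit (default 1e-7).
#' @param identityMinPct hits must exceed this percent identity (default 20).
#' @param databaseSizeAA effective database size in residues; `NA` (default)
#'   means the summed length of the screened proteome.
#' @return a [ScreenConfig-class].
#' @export
screenConfig <- function(evalueMax = 1e-7, identityMinPct = 20,
                         databaseSizeAA = NA_real_) {
  new("ScreenConfig", evalueMax = evalueMax, identityMinPct = identityMinPct,
      databaseSizeAA = databaseSizeAA)
}

# identity over alignment columns; gap columns count in the denominator and
# X never counts as identical.
alignmentIdentity <- function(pa, ps) {
  a <- strsplit(pa, "", fixed = TRUE)[[1L]]
  b <- strsplit(ps, "", fixed = TRUE)[[1L]]
  ident <- sum(a == b & a != "-" & a != "X")
  cols <- length(a)
  list(identity_pct = 100 * ident / cols, aligned_cols = cols)
}

kaEvalue <- function(score, m, n, scheme) {
  scheme@K * m * n * exp(-scheme@lambda * score)
}

#' Align two proteins
#'
#' Optimal affine-gap alignment (Smith-Waterman local or Needleman-Wunsch
#' global) of two protein sequences under a [ScoringScheme-class]. Percent
#' identity is computed over alignment columns (gap columns included in the
#' denominator; `X` never counts as identical) and the E-value follows
#' Karlin-Altschul statistics, `E = K m n exp(-lambda S)` with `m` the query
#' length and `n` the database size in residues.
#'
#' @param a,b query and target: character, [Biostrings::AAString], or
#'   length-1 `AAStringSet`.
#' @param scheme a [ScoringScheme-class].
#' @param mode `"local"` (default) or `"global"`.
#' @param databaseSizeAA database size for the E-value; defaults to the
#'   target length.
#' @param queryId,targetId identifiers for the result row; default to the
#'   sequence names when present.
#' @return a one-row [S4Vectors::DataFrame] with columns `query_id`,
#'   `target_id`, `score`, `identity_pct`, `aligned_cols`, `qstart`, `qend`,
#'   `tstart`, `tend` (1-based residue spans) and `evalue`.
#' @export
alignPair <- function(a, b, scheme = scoringScheme(),
                      mode = c("local", "global"),
                      databaseSizeAA = NULL,
                      queryId = NULL, targetId = NULL) {
  mode <- match.arg(mode)
  if (is.null(queryId)) queryId <- names(a) %||% "query"
  if (is.null(targetId)) targetId <- names(b) %||% "target"
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  checkAASeq(a, "query"); checkAASeq(b, "target")
  if (is.null(databaseSizeAA)) databaseSizeAA <- nchar(b)
  aln <- pairwiseAlignment(AAString(a), AAString(b),
                           substitutionMatrix = scheme@matrix,
                           gapOpening = scheme@gapOpen,
                           gapExtension = scheme@gapExtend,
                           type = mode)
  pa <- as.character(alignedPattern(aln))
  ps <- as.character(alignedSubject(aln))
  idn <- alignmentIdentity(pa, ps)
  sc <- score(aln)
  DataFrame(query_id = queryId, target_id = targetId,
            score = sc,
            identity_pct = idn$identity_pct,
            aligned_cols = idn$aligned_cols,
            qstart = start(aln@pattern@range), qend = end(aln@pattern@range),
            tstart = start(aln@subject@range), tend = end(aln@subject@range),
            evalue = kaEvalue(sc, nchar(a), databaseSizeAA, scheme))
}

#' Screen a proteome with a driver protein
#'
#' Aligns the driver against every target and returns all and only the
#' targets with `evalue <= evalueMax` and `identity_pct > identityMinPct`,
#' sorted by ascending E-value. The E-value database size is the summed
#' proteome length unless fixed in the [ScreenConfig-class].
#'
#' @param driver a named length-1 [Biostrings::AAStringSet] (or AAString /
#'   character) query.
#' @param proteome an [Biostrings::AAStringSet], typically from
#'   [extractProteome()] (its `mcols` `genome`/`locus_tag` propagate).
#' @param scheme a [ScoringScheme-class].
#' @param cfg a [ScreenConfig-class].
#' @param role role hypothesis inherited by hits (e.g. `"LanB"`, `"LanC"`);
#'   default `NA`.
#' @return a [S4Vectors::DataFrame] of hits: alignment columns plus
#'   `genome`, `locus_tag`, `role_hypothesis`.
#' @export
screenProteome <- function(driver, proteome, scheme = scoringScheme(),
                           cfg = screenConfig(), role = NA_character_) {
  if (length(proteome) == 0L) stop("proteome must be non-empty")
  dbSize <- cfg@databaseSizeAA
  if (is.na(dbSize)) dbSize <- sum(width(proteome))
  driverId <- names(driver) %||% "driver"
  if (is(driver, "AAStringSet")) driver <- driver[[1L]]
  meta <- mcols(proteome)
  rows <- lapply(seq_along(proteome), function(i) {
    r <- alignPair(as.character(driver), as.character(proteome[[i]]),
                   scheme = scheme, mode = "local",
                   databaseSizeAA = dbSize,
                   queryId = driverId[1L],
                   targetId = names(proteome)[i] %||% paste0("t", i))
    r$genome <- if (!is.null(meta$genome)) meta$genome[i] else NA_character_
    r$locus_tag <- if (!is.null(meta$locus_tag)) meta$locus_tag[i]
                   else names(proteome)[i]
    r
  })
  hits <- do.call(rbind, rows)
  hits$role_hypothesis <- role
  keep <- hits$evalue <= cfg@evalueMax & hits$identity_pct > cfg@identityMinPct
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$evalue, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# screen a set of drivers (AAStringSet with mcols$role) against a list of
# genome proteomes; returns the union of hits.
screenDrivers <- function(drivers, proteomes, scheme, cfg) {
  roles <- mcols(drivers)$role %||% rep(NA_character_, length(drivers))
  out <- list()
  for (d in seq_along(drivers)) {
    for (p in proteomes) {
      if (length(p) == 0L) next
      h <- screenProteome(drivers[d], p, scheme, cfg, role = roles[d])
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(emptyHits())
  do.call(rbind, out)
}

emptyHits <- function() {
  DataFrame(query_id = character(), target_id = character(),
            score = numeric(), identity_pct = numeric(),
            aligned_cols = integer(), qstart = integer(), qend = integer(),
            tstart = integer(), tend = integer(), evalue = numeric(),
            genome = character(), locus_tag = character(),
            role_hypothesis = character())
}

# deduplicate hits by (genome, locus_tag), keeping the lowest E-value row.
dedupHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$genome, hits$locus_tag, sep = "\r")
  hits <- hits[order(hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$genome, hits$locus_tag, sep = "\r")), ,
               drop = FALSE]
  hits <- hits[order(hits$genome, hits$evalue), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Iterative driver expansion
#'
#' Screens the genomes with the seed drivers, then re-screens using every
#' newly found protein as a driver (inheriting the role hypothesis of the
#' driver that found it), until a round yields no new hit or `maxRounds` is
#' reached. The hit set is the union across rounds, deduplicated by
#' (genome, locus tag).
#'
#' @param seedDrivers named [Biostrings::AAStringSet] with `mcols` column
#'   `role`.
#' @param genomes list of [GenomeRecord-class].
#' @param scheme a [ScoringScheme-class].
#' @param cfg a [ScreenConfig-class].
#' @param maxRounds maximum number of screening rounds (>= 1).
#' @return a list with `hits` (DataFrame as in [screenProteome()], plus a
#'   `round` column recording the round of first discovery) and
#'   `roundsUsed`.
#' @export
iterativeExpand <- function(seedDrivers, genomes, scheme = scoringScheme(),
                            cfg = screenConfig(), maxRounds = 3L) {
  stopifnot(maxRounds >= 1L)
  proteomes <- lapply(genomes, extractProteome)
  names(proteomes) <- vapply(genomes, accession, character(1))
  allHits <- emptyHits()
  allHits$round <- integer()
  drivers <- seedDrivers
  seen <- character()
  roundsUsed <- 0L
  for (r in seq_len(maxRounds)) {
    if (length(drivers) == 0L) break
    roundsUsed <- r
    h <- screenDrivers(drivers, proteomes, scheme, cfg)
    h <- dedupHits(h)
    key <- paste(h$genome, h$locus_tag, sep = "\r")
    new <- h[!key %in% seen, , drop = FALSE]
    if (nrow(new) == 0L) break
    new$round <- r
    seen <- c(seen, paste(new$genome, new$locus_tag, sep = "\r"))
    allHits <- rbind(allHits, new)
    # next round's drivers: the proteins first found this round
    drivers <- do.call(c, lapply(seq_len(nrow(new)), function(i) {
      p <- proteomes[[new$genome[i]]]
      s <- p[match(new$locus_tag[i], mcols(p)$locus_tag)]
      mcols(s) <- DataFrame(role = new$role_hypothesis[i])
      s
    }))
  }
  allHits <- allHits[order(allHits$genome, allHits$evalue), , drop = FALSE]
  rownames(allHits) <- NULL
  list(hits = allHits, roundsUsed = roundsUsed)
}
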