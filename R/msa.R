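# Built-in progressive multiple alignment: neighbor-joining guide tree on
# k-mer distances, profile-profile merges by global affine-gap DP (C++
# kernel), plus an adapter for externally aligned FASTA.

PROFILE_LETTERS <- c(AA20, "X")

# residue-frequency profile of a set of gapped rows (character vector).
# 21 x L matrix of per-column frequencies over sequences (gaps excluded
# from the numerator but rows stay in the denominator, so gap-heavy
# columns score low).
profileOf <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  p <- matrix(0, nrow = length(PROFILE_LETTERS), ncol = L,
              dimnames = list(PROFILE_LETTERS, NULL))
  for (k in seq_along(PROFILE_LETTERS))
    p[k, ] <- colSums(mat == PROFILE_LETTERS[k])
  p / length(rows)
}

mergeProfiles <- function(rowsA, rowsB, submat, gapOpen, gapExtend) {
  pA <- profileOf(rowsA)
  pB <- profileOf(rowsB)
  S <- submat[PROFILE_LETTERS, PROFILE_LETTERS]
  M <- t(pA) %*% S %*% pB
  res <- .gotoh_profile(M, gapOpen, gapExtend)
  path <- res$path
  gapA <- strrep("-", 1L)
  outA <- character(length(path))
  outB <- character(length(path))
  ai <- 0L; bi <- 0L
  takeA <- path != 2L
  takeB <- path != 1L
  idxA <- cumsum(takeA)
  idxB <- cumsum(takeB)
  newRows <- function(rows, take, idx) {
    chs <- strsplit(rows, "", fixed = TRUE)
    vapply(chs, function(ch) {
      out <- rep("-", length(take))
      out[take] <- ch[idx[take]]
      paste(out, collapse = "")
    }, character(1))
  }
  list(rows = c(newRows(rowsA, takeA, idxA), newRows(rowsB, takeB, idxB)),
       score = res$score)
}

# fraction-of-shared-k-mers distance used for the guide tree
kmerDistance <- function(seqs, k = 3L) {
  n <- length(seqs)
  sets <- lapply(seqs, function(s) {
    s <- as.character(s)
    if (nchar(s) < k) return(s)
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    denom <- min(length(sets[[i]]), length(sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1L)
  }
  d
}

#' Build a multiple sequence alignment
#'
#' The built-in aligner is a progressive aligner: pairwise guide distances
#' from shared k-mer fractions, a neighbor-joining guide tree, and
#' profile-profile merges by global affine-gap dynamic programming (end
#' gaps penalized) under the scheme's substitution matrix. The `external`
#' adapter reads an aligned FASTA produced by any external tool (e.g.
#' MUSCLE or MAFFT).
#'
#' @param seqs named [Biostrings::AAStringSet] (or named character vector),
#'   at least 2 sequences, unique names.
#' @param aligner `"builtin"` (default) or `"external"`.
#' @param alignedPath path to an aligned FASTA, required for
#'   `aligner = "external"`.
#' @param scheme a [ScoringScheme-class] (substitution matrix and gap
#'   penalties for the profile DP).
#' @return an [Biostrings::AAMultipleAlignment] with rownames preserved.
#' @export
buildMsa <- function(seqs, aligner = c("builtin", "external"),
                     alignedPath = NULL, scheme = scoringScheme()) {
  aligner <- match.arg(aligner)
  if (aligner == "external") {
    if (is.null(alignedPath)) stop("alignedPath required for external MSA")
    aln <- readAAStringSet(alignedPath)
    return(AAMultipleAlignment(aln))
  }
  if (is.character(seqs)) seqs <- AAStringSet(seqs)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  for (i in seq_len(n)) checkAASeq(seqs[[i]], ids[i])
  clusters <- lapply(seq_len(n), function(i)
    list(ids = ids[i], rows = as.character(seqs[[i]])))
  if (n == 2L) {
    order <- matrix(c(1L, 2L), nrow = 1L)
  } else {
    d <- kmerDistance(seqs)
    dimnames(d) <- list(ids, ids)
    order <- njJoinOrder(d)
  }
  active <- seq_len(n)
  for (r in seq_len(nrow(order))) {
    i <- order[r, 1L]; j <- order[r, 2L]
    mg <- mergeProfiles(clusters[[i]]$rows, clusters[[j]]$rows,
                        scheme@matrix, scheme@gapOpen, scheme@gapExtend)
    clusters[[i]] <- list(ids = c(clusters[[i]]$ids, clusters[[j]]$ids),
                          rows = mg$rows)
    clusters[[j]] <- NULL_CLUSTER
  }
  final <- clusters[[order[nrow(order), 1L]]]
  rows <- final$rows[match(ids, final$ids)]
  out <- AAStringSet(rows)
  names(out) <- ids
  AAMultipleAlignment(out)
}

NULL_CLUSTER <- list(ids = character(), rows = character())

# msa utility: matrix of characters with rownames
msaMatrix <- function(m) {
  x <- as.character(unmasked(m))
  mat <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(mat) <- names(unmasked(m))
  mat
}

#' Drop gaps from one alignment row
#'
#' @param m an [Biostrings::AAMultipleAlignment].
#' @param id row name.
#' @return the ungapped sequence (character).
#' @export
ungapRow <- function(m, id) {
  x <- as.character(unmasked(m))
  if (!id %in% names(x)) stop("unknown id: ", id)
  gsub("-", "", x[[id]], fixed = TRUE)
}
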