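# Distance-based phylogenetics: p-distance / Poisson-corrected distances
# from an MSA, Saitou-Nei neighbor joining with deterministic tie-breaks,
# and phylogroup extraction by cutting long edges.

#' Pairwise distances from a multiple alignment
#'
#' p-distance: mismatches over shared non-gap columns; Poisson correction:
#' `-ln(1 - p)`.
#'
#' @param m an [Biostrings::AAMultipleAlignment] (>= 3 rows for tree
#'   building; >= 2 accepted here).
#' @param model `"p"` (default) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
distanceMatrix <- function(m, model = c("p", "poisson")) {
  model <- match.arg(model)
  mat <- msaMatrix(m)
  n <- nrow(mat)
  ids <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  notGap <- mat != "-"
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    sh <- notGap[i, ] & notGap[j, ]
    ns <- sum(sh)
    if (ns == 0L)
      stop("rows ", ids[i], " and ", ids[j], " share no aligned columns")
    p <- sum(mat[i, sh] != mat[j, sh]) / ns
    v <- if (model == "p") p else {
      if (p >= 1) stop("Poisson correction undefined at p = 1")
      -log(1 - p)
    }
    d[i, j] <- d[j, i] <- v
  }
  d
}

# NJ core: returns per-step joins and newick. Tie-breaks: among equal-Q
# pairs, the pair whose (lexicographically smallest member id, then second
# id) sorts first.
njCore <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  stopifnot(n >= 3L, identical(ids, colnames(d)))
  active <- seq_len(n)
  nwk <- ids                     # newick fragment per slot
  repId <- ids                     # smallest member id per slot (tie-break)
  joins <- matrix(0L, nrow = n - 2L, ncol = 2L)
  D <- d
  step <- 0L
  while (length(active) > 3L) {
    N <- length(active)
    r <- rowSums(D[active, active, drop = FALSE])
    names(r) <- as.character(active)
    best <- NULL
    for (a in seq_len(N - 1L)) for (b in seq.int(a + 1L, N)) {
      i <- active[a]; j <- active[b]
      q <- (N - 2) * D[i, j] - r[as.character(i)] - r[as.character(j)]
      key <- sort(c(repId[i], repId[j]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
        best <- list(q = q, i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[as.character(i)] - r[as.character(j)]) / (2 * (N - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    step <- step + 1L
    joins[step, ] <- c(i, j)
    # new node lives in slot i
    newD <- (D[i, active] + D[j, active] - D[i, j]) / 2
    D[i, active] <- newD
    D[active, i] <- newD
    D[i, i] <- 0
    nwk[i] <- sprintf("(%s:%.17g,%s:%.17g)", nwk[i], li, nwk[j], lj)
    repId[i] <- min(repId[i], repId[j])
    active <- setdiff(active, j)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  step <- step + 1L
  joins[step, ] <- c(a, b)
  newick <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                    nwk[a], la, nwk[b], lb, nwk[c3], lc)
  list(newick = newick, joins = joins[seq_len(step), , drop = FALSE],
       last3 = c(a, b, c3))
}

# join order for progressive alignment: successive (slotA, slotB) merges,
# ending with everything merged into one slot.
njJoinOrder <- function(d) {
  n <- nrow(d)
  if (n == 3L) {
    core <- list(joins = matrix(integer(), 0, 2), last3 = 1:3)
  } else core <- njCore(d)
  joins <- core$joins
  if (n > 3L) joins <- joins[-nrow(joins), , drop = FALSE]
  l3 <- core$last3
  rbind(joins,
        c(l3[1L], l3[2L]),
        c(l3[1L], l3[3L]))
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with the Q criterion. Ties between
#' equal-Q pairs break to the lexicographically smallest id pair; negative
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' edge so leaf-to-leaf path lengths are preserved.
#'
#' @param d symmetric distance matrix with dimnames (>= 3 taxa).
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  core <- njCore(d)
  ape::read.tree(text = core$newick)
}

#' Cut a tree into phylogroups
#'
#' Removes the longest edges one at a time (preferring a removal that
#' actually splits the leaf set) until the leaves fall into `k` connected
#' groups. Deterministic: edges are taken in order of decreasing length,
#' then by position in the tree's edge table.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param k number of groups (1 <= k <= number of leaves).
#' @return list of phylogroups, each a list with `label` and `members`
#'   (tip labels); groups are ordered and labelled "1", "2", ... by their
#'   smallest member id.
#' @export
extractPhylogroups <- function(tree, k) {
  ntip <- length(tree$tip.label)
  stopifnot(k >= 1L, k <= ntip)
  edges <- tree$edge
  lens <- tree$edge.length
  ord <- order(-lens, seq_along(lens))
  removed <- logical(length(lens))
  nodes <- max(edges)
  leafGroups <- function() {
    # components over the forest of non-removed edges
    parent <- seq_len(nodes)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (e in which(!removed)) {
      a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
      if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_len(ntip), function(t) find(t), integer(1))
    split(tree$tip.label, comp)
  }
  groups <- leafGroups()
  for (e in ord) {
    if (length(groups) >= k) break
    removed[e] <- TRUE
    newGroups <- leafGroups()
    if (length(newGroups) > length(groups)) groups <- newGroups
    else removed[e] <- FALSE
  }
  groups <- groups[order(vapply(groups, min, character(1)))]
  lapply(seq_along(groups), function(i)
    list(label = as.character(i), members = sort(unname(groups[[i]]))))
}

#' Write a distance matrix in PHYLIP format
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhylipDist <- function(d, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(sprintf("%-10s", substr(rownames(d)[i], 1L, 10L)),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}
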