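# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Keeps package randomness out of the user session.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

aaChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]

checkAASeq <- function(x, what = "sequence", allowStop = FALSE) {
  ch <- aaChars(x)
  ok <- c(AA20, "X", if (allowStop) "*")
  bad <- setdiff(unique(ch), ok)
  if (length(bad))
    stop(what, " contains illegal symbol(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Sorted, validated GenomeRecord constructor.

#' Construct a GenomeRecord
#'
#' @param accession single character identifier.
#' @param sequence nucleotide sequence (character or [Biostrings::DNAString]).
#' @param features `DataFrame`/`data.frame` of CDS features with columns
#'   `locus_tag`, `start`, `end` (0-based half-open), `strand` (+1/-1),
#'   `translation`, `product`. May be missing columns `translation`/`product`
#'   (filled with `NA`). Rows are re-sorted by `start`.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return a [GenomeRecord-class] object.
#' @export
GenomeRecord <- function(accession, sequence, features = NULL,
                         topology = "linear") {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (is.null(features))
    features <- DataFrame(locus_tag = character(), start = integer(),
                          end = integer(), strand = integer(),
                          translation = character(), product = character())
  features <- as(features, "DataFrame")
  if (is.null(features$translation)) features$translation <- NA_character_
  if (is.null(features$product)) features$product <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  new("GenomeRecord", accession = accession, sequence = sequence,
      features = features, topology = topology)
}

#' @rdname GenomeRecord-class
#' @export
setMethod("accession", "GenomeRecord", function(x) x@accession)

#' @rdname GenomeRecord-class
#' @export
setMethod("genomeSequence", "GenomeRecord", function(x) x@sequence)

#' @rdname GenomeRecord-class
#' @export
setMethod("features", "GenomeRecord", function(x) x@features)

#' @rdname GenomeRecord-class
#' @export
setMethod("topology", "GenomeRecord", function(x) x@topology)

#' @rdname GenomeRecord-class
#' @export
setMethod("length", "GenomeRecord", function(x) length(x@sequence))

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@accession, "|",
      length(object@sequence), "bp", object@topology, "|",
      nrow(object@features), "CDS\n")
})

#' @rdname GeneCluster-class
#' @export
setMethod("members", "GeneCluster", function(x) x@members)

#' @rdname GeneCluster-class
#' @export
setMethod("classification", "GeneCluster", function(x) x@classification)

#' @rdname GeneCluster-class
#' @export
setMethod("clusterSpan", "GeneCluster", function(x) x@span)

setMethod("show", "GeneCluster", function(object) {
  cat("GeneCluster on", object@genome,
      sprintf("[%d, %d)", object@span[1L], object@span[2L]),
      "|", object@classification, "|", nrow(object@members), "members:",
      paste(object@members$role, collapse = ", "), "\n")
})

setMethod("show", "ScreenReport", function(object) {
  s <- object@summary
  cat("ScreenReport:", s$n_clusters, "clusters (",
      s$n_complete, "complete,", s$n_nolana, "lanA-less,",
      s$n_orphan, "orphan,", s$n_multi_lanc, "multi-lanC ) from",
      s$n_hits, "homolog hits in", s$rounds_used, "screening round(s)\n")
})

#' @rdname ScreenReport-class
#' @param x a `ScreenReport`.
#' @export
reportRows <- function(x) x@rows

#' @rdname ScreenReport-class
#' @export
reportSummary <- function(x) x@summary

#' @rdname ScreenReport-class
#' @export
reportClusters <- function(x) x@clusters
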