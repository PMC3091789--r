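#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAString AAString AAStringSet
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom BiocGenerics start end width strand
#' @importFrom IRanges IRanges reduce gaps
#' @importFrom Biostrings DNAString AAString AAStringSet DNAStringSet
#'   reverseComplement translate subseq readAAStringSet writeXStringSet
#'   AAMultipleAlignment pairwiseAlignment alignedPattern alignedSubject
#'   unmasked width xscat
#' @importFrom stats runif
#' @importFrom utils write.table read.table
NULL

# The 20 canonical amino acids, fixed order used by profiles and matrices.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' An annotated replicon
#'
#' `GenomeRecord` holds one replicon (chromosome, plasmid or contig): its
#' nucleotide sequence, its CDS features, and its topology. Coordinates are
#' stored 0-based half-open internally; the GenBank reader/writer convert to
#' and from GenBank's 1-based inclusive convention at the I/O boundary.
#'
#' @slot accession single character identifier.
#' @slot sequence a [Biostrings::DNAString] over A,C,G,T,N.
#' @slot features a [S4Vectors::DataFrame] with one row per CDS, columns
#'   `locus_tag`, `start`, `end` (0-based half-open), `strand` (+1/-1),
#'   `translation`, `product`. Rows are sorted by `start`.
#' @slot topology `"linear"` or `"circular"`.
#'
#' @seealso [readGenBank()], [extractProteome()], [intergenicRegions()]
#' @export
setClass("GenomeRecord",
  representation(
    accession = "character",
    sequence  = "DNAString",
    features  = "DataFrame",
    topology  = "character"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@accession) != 1L || !nzchar(object@accession))
    msg <- c(msg, "'accession' must be a single non-empty string")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "'topology' must be 'linear' or 'circular'")
  f <- object@features
  need <- c("locus_tag", "start", "end", "strand", "translation", "product")
  if (!all(need %in% colnames(f))) {
    msg <- c(msg, paste0("features must have columns: ",
                         paste(need, collapse = ", ")))
  } else if (nrow(f) > 0L) {
    if (any(f$start < 0L) || any(f$end > length(object@sequence)))
      msg <- c(msg, "feature coordinates out of range")
    if (any(f$end <= f$start))
      msg <- c(msg, "features must have end > start")
    if (is.unsorted(f$start))
      msg <- c(msg, "features must be sorted by start")
    if (anyDuplicated(f$locus_tag))
      msg <- c(msg, "locus_tag values must be unique")
    if (!all(f$strand %in% c(1L, -1L)))
      msg <- c(msg, "strand must be +1 or -1")
  }
  if (length(msg)) msg else TRUE
})

#' Protein-alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties and Karlin-Altschul
#' parameters for E-value computation. The default mirrors blastp defaults:
#' BLOSUM62, gap open 11, gap extend 1, with the published gapped-search
#' constants lambda = 0.267, K = 0.041. A gap of length L costs
#' `gapOpen + L * gapExtend`.
#'
#' @slot matrix 20+ letter integer substitution matrix.
#' @slot gapOpen,gapExtend non-negative penalties.
#' @slot lambda,K Karlin-Altschul parameters for `E = K m n exp(-lambda S)`.
#' @export
setClass("ScoringScheme",
  representation(
    matrix = "matrix",
    gapOpen = "numeric",
    gapExtend = "numeric",
    lambda = "numeric",
    K = "numeric"
  )
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (object@gapExtend < 0 || object@gapOpen < object@gapExtend)
    msg <- c(msg, "need gapOpen >= gapExtend >= 0")
  m <- object@matrix
  if (!isTRUE(all.equal(m, t(m))))
    msg <- c(msg, "substitution matrix must be symmetric")
  if (object@lambda <= 0 || object@K <= 0)
    msg <- c(msg, "lambda and K must be positive")
  if (length(msg)) msg else TRUE
})

#' Homology-screen thresholds
#'
#' A target is reported as a homolog when its alignment E-value is at most
#' `evalueMax` and its percent identity is strictly greater than
#' `identityMinPct` (identity computed over alignment columns, gap columns
#' included in the denominator).
#'
#' @slot evalueMax maximum E-value (default 1e-7).
#' @slot identityMinPct identity must exceed this percentage (default 20).
#' @slot databaseSizeAA effective database size in residues used for the
#'   E-value; `NA` means "sum of target proteome lengths, computed per
#'   screen".
#' @export
setClass("ScreenConfig",
  representation(
    evalueMax = "numeric",
    identityMinPct = "numeric",
    databaseSizeAA = "numeric"
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@evalueMax <= 0) msg <- c(msg, "evalueMax must be > 0")
  if (object@identityMinPct < 0 || object@identityMinPct > 100)
    msg <- c(msg, "identityMinPct must be in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' LanA candidate-scoring configuration
#'
#' Thresholds for the precursor-peptide (LanA) heuristic: a candidate passes
#' when its length lies in `[minAA, maxAA]`, it contains at least one
#' cysteine, the S+T+C fraction of its propeptide is at least
#' `stcFractionMin`, and the S+T+C density difference between propeptide and
#' leader (the "skew") is at least `stcSkewMin`.
#'
#' @slot minAA,maxAA length bounds in amino acids.
#' @slot stcFractionMin minimum propeptide S+T+C fraction.
#' @slot stcSkewMin minimum propeptide-minus-leader S+T+C density difference.
#' @slot minLeader,minPropeptide bounds on the leader/propeptide split search.
#' @export
setClass("LanaConfig",
  representation(
    minAA = "integer",
    maxAA = "integer",
    stcFractionMin = "numeric",
    stcSkewMin = "numeric",
    minLeader = "integer",
    minPropeptide = "integer"
  )
)

#' A candidate or confirmed lantibiotic gene cluster
#'
#' A genomic window grouping LanB/LanC homolog hits, LanA candidates and
#' accessory genes, with a classification mirroring the screen's reporting
#' categories.
#'
#' @slot genome accession of the replicon.
#' @slot span two integers, 0-based half-open window covering all members.
#' @slot members [S4Vectors::DataFrame] with columns `id`, `role`, `start`,
#'   `end`, `strand`, `identity_pct`, `evalue`, `provenance`.
#' @slot classification one of `"COMPLETE"`, `"NO_LANA"`, `"ORPHAN"`,
#'   `"MULTI_LANC_NO_A"`.
#' @export
setClass("GeneCluster",
  representation(
    genome = "character",
    span = "integer",
    members = "DataFrame",
    classification = "character"
  )
)

setValidity("GeneCluster", function(object) {
  msg <- character()
  if (length(object@span) != 2L || object@span[2L] <= object@span[1L])
    msg <- c(msg, "span must be two increasing integers")
  m <- object@members
  if (nrow(m) > 0L &&
      (min(m$start) < object@span[1L] || max(m$end) > object@span[2L]))
    msg <- c(msg, "span must cover all members")
  if (length(msg)) msg else TRUE
})

#' End-to-end screen report
#'
#' Result container for [runPipeline()]: one row per cluster member across
#' all genomes plus summary counts.
#'
#' @slot rows [S4Vectors::DataFrame]: genome, cluster id, classification,
#'   member id, role, coordinates, identity to driver.
#' @slot summary named list of counts (`n_complete`, `n_nolana`, `n_orphan`,
#'   `n_multi_lanc`, `n_clusters`, `n_hits`, `rounds_used`).
#' @slot clusters list of [GeneCluster-class] objects.
#' @export
setClass("ScreenReport",
  representation(
    rows = "DataFrame",
    summary = "list",
    clusters = "list"
  )
)
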