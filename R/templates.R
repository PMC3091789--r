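# Template library for the synthetic-genome generator: exemplar LanB/LanC
# enzymes carrying the canonical conserved motifs at their reference
# (NisB/NisC) positions, known type 1 precursor peptides, synthetic
# accessory-family exemplars, and decoy proteins.

TEMPLATE_SEED <- 90217L  # fixed: the library is a package constant

randomProtein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# overwrite the anchored (non-wildcard) letters of a motif set into `seq`;
# returns the sequence and the protected positions.
imprintMotifs <- function(seq, defs) {
  ch <- aaChars(seq)
  protected <- integer()
  for (i in seq_len(nrow(defs))) {
    pat <- aaChars(defs$pattern[i])
    pos <- defs$ref_start[i]:defs$ref_end[i]
    anchored <- pat != "x"
    ch[pos[anchored]] <- pat[anchored]
    protected <- c(protected, pos[anchored])
  }
  list(seq = paste(ch, collapse = ""), protected = sort(unique(protected)))
}

#' The packaged template library
#'
#' Deterministic exemplar proteins used by [generateGenome()] and as
#' default screen drivers:
#' * `lanB` — a synthetic ~1000-aa lanthionine dehydratase carrying the
#'   canonical NisB-numbered motifs ([nisbMotifs()]) and single residues at
#'   their reference positions;
#' * `lanC` — a synthetic 420-aa cyclase carrying the NisC-numbered motifs
#'   ([niscMotifs()]) including the CHG zinc-ligand and WCYG motifs;
#' * `lanA` — known type 1 precursor prepropeptides (nisin A, subtilin,
#'   epidermin, gallidermin, Pep5) read from the packaged FASTA, plus the
#'   nisin precursor as the planting template;
#' * `accessory` — synthetic exemplars for the accessory families
#'   (LanT transporter, LanP protease, LanEFG immunity, LanKR two-component
#'   pair, LanD decarboxylase, O-methyltransferase); these are synthetic
#'   stand-ins, not database sequences;
#' * `protected` — per-template positions shielded from mutation (motif
#'   anchors; for the LanA template the propeptide Ser/Thr/Cys and leader
#'   DLD, mirroring the functional residues real families conserve).
#'
#' @return a named list as described above.
#' @export
templateLibrary <- function() {
  withLocalSeed(TEMPLATE_SEED, {
    lanB0 <- randomProtein(1000L)
    bAll <- rbind(nisbMotifs(), nisbResidues())
    bimp <- imprintMotifs(lanB0, bAll)
    lanB <- bimp$seq

    lanC0 <- randomProtein(420L)
    cAll <- rbind(niscMotifs(), niscResidues())
    cimp <- imprintMotifs(lanC0, cAll)
    lanC <- cimp$seq

    fa <- readAAStringSet(system.file("extdata", "lana_known.faa",
                                      package = "lantimine", mustWork = TRUE))
    names(fa) <- sub(" .*", "", names(fa))
    lanA <- as.character(fa)
    plant <- lanA[["NisA"]]
    plantSplit <- 23L  # nisin leader length
    stcPos <- which(aaChars(plant) %in% c("S", "T", "C"))
    stcPos <- stcPos[stcPos > plantSplit]
    dld <- as.integer(gregexpr("DLD", substr(plant, 1L, plantSplit))[[1L]])
    dldPos <- if (dld[1L] > 0L) as.integer(outer(dld, 0:2, `+`)) else integer()
    plantProt <- sort(unique(c(stcPos, dldPos)))

    accessory <- AAStringSet(c(
      LanT = randomProtein(590L), LanP = randomProtein(500L),
      LanEFG = randomProtein(250L), LanKR = randomProtein(450L),
      LanD = randomProtein(180L), OMT = randomProtein(260L)))

    list(
      lanB = AAStringSet(c(LanB_template = lanB)),
      lanC = AAStringSet(c(LanC_template = lanC)),
      lanA = fa,
      lanAPlant = AAStringSet(c(LanA_template = plant)),
      accessory = accessory,
      protected = list(LanB_template = bimp$protected,
                       LanC_template = cimp$protected,
                       LanA_template = plantProt)
    )
  })
}

#' Default screen drivers
#'
#' The template dehydratase and cyclase with their role hypotheses, for
#' seeding [runPipeline()] / [iterativeExpand()].
#'
#' @param lib a [templateLibrary()] (built if missing).
#' @return [Biostrings::AAStringSet] with `mcols` column `role`.
#' @export
defaultDrivers <- function(lib = templateLibrary()) {
  d <- c(lib$lanB, lib$lanC)
  mcols(d) <- DataFrame(role = c("LanB", "LanC"))
  d
}
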