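---
title: "Mining type 1 lantibiotic gene clusters: models and methods"
author: "lantimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining type 1 lantibiotic gene clusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lantimine)
```

## The biological problem

Type 1 lantibiotics are ribosomally synthesised, post-translationally
modified antimicrobial peptides. The structural gene (*lanA*) encodes a
prepropeptide: an N-terminal leader that is eventually cleaved and a
C-terminal propeptide in which serines and threonines are dehydrated by a
lanthionine dehydratase (LanB) and then cyclised onto cysteines by a
lanthionine cyclase (LanC), forming the thioether (lanthionine) rings that
give the class its name. The biosynthetic genes travel together: a typical
locus holds *lanA*, *lanB*, *lanC* and assorted accessory genes
(transporter LanT, leader protease LanP, immunity proteins LanEFG, the
LanK/LanR two-component pair, occasionally a LanD decarboxylase or an
O-methyltransferase).

Because LanB and LanC are long, well-conserved enzymes while LanA is a
short, poorly conserved peptide that annotation pipelines routinely miss,
the productive mining strategy is: find the *enzymes* by homology, then
hunt for the precursor *around* them — including in DNA that carries no
gene call at all. `lantimine` implements that strategy end to end, plus
the downstream comparative analyses (reference-anchored motif
conservation, neighbor-joining phylogroups) that such screens report.

## The screen

### Homology detection

`alignPair()` computes optimal pairwise alignments (Smith–Waterman local
by default, Needleman–Wunsch global on request) under BLOSUM62 with
affine gap penalties (open 11, extend 1), delegating the dynamic program
to `Biostrings::pairwiseAlignment`. Significance follows Karlin–Altschul
statistics,

$$E = K \, m \, n \, e^{-\lambda S},$$

with the published gapped-search constants for this scoring scheme
($\lambda = 0.267$, $K = 0.041$), $m$ the query length and $n$ the
database size in residues (by default the summed length of the screened
proteome). A target is a homolog when $E \le 10^{-7}$ **and** percent
identity exceeds 20. Identity is computed over alignment columns — gap
columns count in the denominator, and `X` never counts as identical. The
identity denominator is a genuinely open choice (alignment length versus
query length); the package uses alignment length and keeps the threshold
configurable in `screenConfig()`.

`iterativeExpand()` re-screens with every newly found protein as a driver
until a round adds nothing. Hits are deduplicated by (genome, locus tag)
and keep the role hypothesis (LanB or LanC) of the driver that found
them; the hit set is monotonically non-decreasing over rounds and the
procedure is a fixed-point iteration, so it terminates.

### Precursor discovery

`findLanaCandidates()` scores two candidate pools within a window
(default 10 kb, the scale of "close genomic association" for bacterial
operons) around each LanB/LanC anchor: annotated CDS short enough to be a
precursor, and every maximal start-to-stop open reading frame from the
six-frame translation of intergenic (CDS-free) DNA. ATG, GTG and TTG are
accepted as starts (bacterial reality) and translated as Met; an ORF is
maximal when its start is the first start codon after the preceding
in-frame stop.

The filter (`scoreLana()`) operationalises what makes a type 1 precursor
recognisable: short length (bounds 20–120 aa; the family centres near
60 aa but spans roughly 43–86), at least one cysteine (no thioether
without one), and an *uneven* distribution of Ser/Thr/Cys — the
propeptide is S/T/C-rich because those residues become the rings, while
the leader is not. `splitLeader()` finds the leader/propeptide boundary
as the split maximising the difference in S+T+C density between the two
sides, searched over the central 25–75% of the peptide (leader at least
6 aa, propeptide at least 10 aa, ties to the smallest index). A candidate
passes when the propeptide S+T+C fraction is at least 0.35 and the skew
(propeptide minus leader density) at least 0.04.

Those two defaults were calibrated once, against two anchors: the
packaged known precursors (nisin A, subtilin, epidermin, gallidermin)
must pass, and uniform-random peptides of the same length must pass at
under 5%. The skew statistic is a maximum over candidate splits and is
therefore inflated under the null, so skew alone cannot separate nisin
(skew 0.17, near the null's upper decile) from noise at 5% specificity;
the propeptide *fraction* (0.42 for nisin versus ≈0.15 expected for
random peptides) carries the specificity, and the skew threshold is kept
low, enforcing only the direction of the bias. A known limitation: the
Pep5 precursor, whose propeptide is unusually S/T/C-poor (fraction 0.27),
does not clear the binary filter — it still ranks by the composite score,
which is how a practitioner would triage borderline candidates. Candidate
ranking uses `2·skew + 0.1·min(cys, 10)` plus motif bonuses (+1 for a
leader DLD box, +0.5 for a late-leader leucine, +0.5 for a CTPGC-like
`C.{2,4}C` pair); bonuses are computed in fixed N-/C-terminal windows so
the composite does not jump when the density split moves.

### Cluster assembly and classification

`assembleClusters()` groups hits and precursor candidates by
single-linkage on the genome axis with the same 10 kb window, then labels
each cluster: `COMPLETE` (lanA + lanB + lanC), `NO_LANA` (both enzymes,
no structural gene), `MULTI_LANC_NO_A` (two or more cyclases, no
precursor — reported separately because it is a biologically distinct
situation), and `ORPHAN` (an isolated homolog). Orphanhood is defined
operationally: no co-clustered lantibiotic-role gene within the window.

Draft genomes sometimes carry a dehydratase split across two ORFs by a
sequencing or authentic frameshift. `mergeFrameshift()` accepts an
adjacent same-strand pair as two halves of one gene when the upstream
part aligns to the reference N-terminus and the downstream part to the
C-terminus, with non-overlapping reference spans, at least 70% combined
coverage, and a combined length within 80–120% of the reference. The
pipeline runs this check on neighbours of every enzyme hit (gap at most
100 nt) before assembly, so a split *lanB* counts as one gene.

`annotateAccessory()` assigns transporter/protease/immunity/regulator/
methyltransferase roles to the remaining genes near a cluster by the same
thresholds as the main screen, against packaged exemplar sequences. The
search region is the member span widened by one window, since accessory
genes flank the core genes rather than sit between them.

## Conservation analysis

`buildMsa()` provides a progressive multiple aligner: guide distances
from shared 3-mer fractions, a neighbor-joining guide tree, and
profile–profile merges by global affine-gap dynamic programming (end gaps
penalised; the column-score matrix is a BLAS matrix product, the Gotoh
recursion is compiled code). For two sequences it reduces to the exact
pairwise optimum, which the tests pin against an independent
implementation. An `external` adapter reads any aligned FASTA, so MUSCLE
or MAFFT output drops in where alignment quality matters.

`motifConservation()` anchors motif definitions to a reference row's own
residue numbering (the field reports dehydratase positions in NisB
numbering and cyclase positions in NisC numbering): reference positions
are mapped to alignment columns through the gap structure, a row contains
a motif when it matches every non-wildcard letter, and percentages are
over all rows, reference included, rounded to integers as the field's
tables print them. Per-letter breakdowns (`breakdown = TRUE`) cover
partially conserved motifs. The canonical dehydratase set (YxxR, RxTPFG,
FxxxYG, GxG, GRF, PxxxRxxNV, RFL, RYG, HxxxNR and single residues) and
cyclase set (LxxG, YDxxxGxxG, GxAHGxxG, WCYG, CHG, GxxxGxxGxxLxL; the CHG
cysteine–histidine pair being the active-site zinc ligands) ship as
`nisbMotifs()`/`niscMotifs()`. One wrinkle: the span commonly cited for
RxTPFG (87–94) is two positions longer than the six-letter pattern; the
package anchors the pattern at 89–94 so every definition satisfies
`length(pattern) == end − start + 1`.

## Phylogenetics

`distanceMatrix()` computes p-distances (mismatches over shared non-gap
columns; a pair sharing no columns is an error, not a zero) or
Poisson-corrected distances. `njTree()` is a from-scratch Saitou–Nei
neighbor joining with two determinism guarantees: ties in the Q criterion
break to the lexicographically smallest id pair, and negative branch
lengths are clamped to zero with the deficit moved to the sibling edge so
leaf-to-leaf path lengths are preserved. On additive matrices it
reproduces the generating tree's topology and path lengths to 1e-9 (and
agrees with `ape::nj`, which serves as an independent cross-check in the
tests, never as the implementation). `extractPhylogroups()` cuts the
longest edges — preferring cuts that actually split the leaf set — until
the requested number of leaf groups exists; with `k` equal to the leaf
count this degenerates to singletons, with `k = 2` it recovers the
two-phylogroup structure this enzyme family shows.

## The synthetic-genome generator

`generateGenome()` builds annotated replicons in which every pipeline
claim is checkable against ground truth. Its defaults are the study
conditions the tests and the acceptance script use:

* planted loci: complete clusters (*lanA*–*lanB*–*lanC* plus one
  accessory gene, alternating transporter and O-methyltransferase),
  lanA-less clusters, and orphan enzymes, on random strands;
* geometry: 50–500 nt gaps within a locus; at least three clustering
  windows (31 kb) of background between loci, so planted clusters can
  never merge;
* templates: a synthetic 1000-aa dehydratase and 420-aa cyclase carrying
  the canonical motifs at their reference positions, the nisin precursor
  as the LanA template, and synthetic accessory exemplars (the accessory
  references are constructed stand-ins, not database sequences);
* divergence: planted proteins are mutated to a target identity with
  BLOSUM62-weighted substitutions; motif anchors and, for the precursor,
  the propeptide S/T/C residues and leader DLD box are protected — the
  residues real families conserve because function depends on them;
* special cases: one precursor written into intergenic DNA with no CDS
  feature (preceded by an in-frame stop so the ORF start is pinned), and
  one dehydratase split 80 aa + remainder across two adjacent CDS;
* background: i.i.d. DNA at GC ≈ 0.5 in which every ORF of ≥ 12 codons
  is disrupted by randomised stop-codon writes iterated to convergence,
  and every background segment is flanked by a short sequence carrying
  stops in all six frames (its own reverse complement), so no reading
  frame survives across segment junctions. This makes spurious precursor
  candidates near planted loci rare by construction — which is what lets
  recovery tests demand sensitivity 1.0 at zero false discoveries.

Codons are drawn uniformly over synonymous choices (no codon-usage
model — irrelevant to the logic under test), except that a non-Met first
codon never uses GTG/TTG, which would re-translate as Met. Everything
derives from one seed; the same spec twice yields byte-identical GenBank
output.

What the generator does *not* emulate: realistic phylogenetic correlation
within families (mutations are i.i.d. given the target identity), codon
bias, overlapping genes, assembly gaps, or annotation noise beyond the
two planted artefacts. Passing the recovery tests therefore demonstrates
the pipeline's logic — thresholds, windows, coordinate handling, merging,
classification — not its performance on real draft genomes, where
annotation quality and compositional heterogeneity add failure modes the
synthetic conditions deliberately exclude.

## Problem sizes and numerical choices

The recovery analyses use 20 genomes of 140 kb with one to two complete
clusters each and family divergence up to 30%; conservation tables are
computed over up to 25 recovered enzymes plus the template reference, and
phylogroup recovery over two 6-member subfamilies simulated from
ancestors at 55% identity. These sizes exercise every code path while
keeping a full run in minutes on one core.

Degenerate inputs are handled explicitly: empty proteomes and empty
genome sets are errors; a genome too short for its requested content
reports the minimum length; a peptide shorter than 20 aa fails the
precursor filter without a split; ambiguous codons translate to `X`,
which never scores as identity; internal stops in annotated translations
are tolerated (draft-genome reality) and logged. All coordinates are
0-based half-open internally, converted to GenBank's 1-based inclusive
convention only at the I/O boundary; that conversion is covered by
round-trip tests.

## Interface

The package's functions are the interface, composable from R or from
`Rscript -e` one-liners: `readGenBank()` / `writeGenBank()` /
`extractProteome()` for I/O, `screenProteome()` / `iterativeExpand()` for
the screen, `findLanaCandidates()`, `assembleClusters()`,
`mergeFrameshift()`, `annotateAccessory()` for assembly,
`buildMsa()` / `motifConservation()` / `njTree()` /
`extractPhylogroups()` for the comparative layer, and `runPipeline()`
for the whole screen with TSV/FASTA/Newick artefacts written per run.
`scripts/acceptance.R` is a worked, runnable example of the complete
analysis.
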