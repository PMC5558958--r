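---
title: "Dissecting the architecture of AT-rich mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the architecture of AT-rich mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

Budding-yeast mitochondrial genomes are small, effectively circular and
extremely AT-rich (around 80% A+T). Their protein-coding complement is
almost frozen — 35 genes: eight proteins, two rRNAs, the RNase P RNA and
24 tRNAs — while everything around the genes churns: intergenic regions
expand and contract, short GC-rich mobile elements ("GC clusters")
insert and vanish, mobile self-splicing introns come and go in *cox1*,
*cob* and *rnl*, and the gene order itself is reshuffled by inversions
and transpositions at rates far exceeding those of the nuclear genome.
`mitoarch` provides the building blocks to quantify each of these layers
on annotated genomes, plus a seeded simulator that generates genomes
with all of these features and the ground truth to score recovery.

## The five-part partition

`buildPartition()` assigns every base pair of a genome to exactly one of
genes, introns or intergenic sequence, and subdivides the intergenic
portion into free-standing ORFs, replication-origin (*ori*) elements,
GC clusters, AT spacers and residual sequence. Published size tables
report these as disjoint quantities without stating how nested elements
are counted (oris, for instance, routinely contain internal GC
clusters), so the package fixes a precedence —
gene > intron > ORF > ori > GC cluster > AT spacer > residual —
and trims lower-precedence intervals. Each base is counted once, making
the two accounting identities exact integer equalities rather than
approximations; they are enforced by the `GenomePartition` validity
method. Consistent with the same precedence, `detectATSpacers()`
excludes annotated ORFs and oris (not just genes and introns) from the
intergenic intervals it fragments.

Coordinates are 1-based closed `IRanges` internally — the native
convention of the R/Bioconductor stack — and 1-based inclusive in all
files; features wrapping the origin of a circular genome are stored as
two ranges sharing a `feature_id`.

## GC-cluster detection: coverage semantics

GC clusters are detected in two passes: windows of at least 16 bp with
GC fraction at least 0.75, then — after masking pass-1 clusters —
windows of at least 8 bp with GC at least 0.85 on the unmasked
remainder, and finally any two clusters separated by fewer than 10 bp
are joined transitively. Two details are underdetermined by that
recipe and are fixed here explicitly:

* **Cluster extent.** A position belongs to a cluster iff it lies in at
  least one qualifying window; clusters are maximal covered runs. This
  "coverage" definition is unambiguous and is checkable against an
  exhaustive oracle that enumerates every qualifying substring (the
  test suite does exactly that, on hundreds of random sequences, and
  for the implementation an $O(n\log n)$ sparse-table formulation
  replaces the $O(n^2)$ enumeration). A consequence worth knowing:
  coverage extends a few bases beyond a GC core whenever a window
  overlapping the AT flank still clears 0.75, so detected clusters are
  slightly wider than their GC cores.
* **Pass-2 windows may abut, but never cross, masked pass-1 clusters.**
* Circular genomes are scanned on the doubled sequence with window
  length capped at the genome length; a cluster wrapping the origin is
  reported with `end` greater than the genome length. "Joined if the
  gap was less than 10 bp" is implemented as gap ≤ 9 bp.
* N bases count as non-GC everywhere.

Thresholds are exact rational comparisons (e.g. 0.75 = 3/4 on integer
counts), so boundary windows are classified identically by the scanner
and the oracle.

## Cluster families

`groupGCClusters()` follows a five-step recipe: pool every cluster with
its reverse complement; compute all-vs-all global-alignment distances
(Needleman–Wunsch, match +1 / mismatch −1 / gap −2, distance
= 1 − identical columns / alignment length); build a UPGMA tree and cut
it at a fixed height; drop a reverse-complement entry whenever its
forward mate shares the group; retain groups greedily by decreasing
size, discarding any group more than 80% of whose members are already
retained; and emit a column-majority consensus per family (ties broken
alphabetically, majority-gap columns dropped). The grouping threshold
is published only as "a threshold"; the default cut height of 0.4
(identity 0.6) is a configuration knob, not a claim. Group consensus
columns come from a deterministic center-star alignment (every member
aligned to the longest member); a full progressive MSA is deliberately
avoided so results do not depend on an external aligner. Family tables
report "main" families at the conventional size cutoff of 8
(`mainFamilies()`).

## Gene order: GOC, bsGOL and DCJ

Gene order conservation between two genomes is the number of shared
orthologue adjacencies divided by the number of shared orthologues,
after restricting both circular orders to their common marker set;
gene-order loss is GOL = 1 − GOC. Adjacencies are unordered neighbour
pairs and blind to strand sign — the markers in practice are whole
transcriptional blocks, so reading direction is not part of the
adjacency relation here.

Branch-specific GOL apportions the $\binom{n}{2}$ pairwise GOL values
over the $2n-3$ branches of the unrooted phylogeny by least squares:
$L = \sum_i (\sum_j b_{ij} x_j - \mathrm{GOL}_i)^2$, where $b_{ij}$
indicates that branch $j$ lies on the path between pair $i$. The
published objective is unconstrained, but negative per-branch loss is
meaningless, so the default solver is non-negative least squares
(`pracma::lsqnonneg`), with the minimum-norm unconstrained solution
available for comparison (`method = "unconstrained"`). Branch rates are
$x_j$ divided by branch length; rates on zero-length branches are
flagged `NA`, and branches crossed by no pair are flagged
unidentifiable.

Rearrangement distances between block orders use the double-cut-and-join
(DCJ) model: $d = N - C$ with $N$ markers and $C$ cycles in the
adjacency graph. DCJ counts minimal operations and is exactly
verifiable (the tests compare it against breadth-first search over all
signed circular 4-marker orders); classifying events into transposition
vs inversion vs inverse transposition, as interactive tools do, is
heuristic and out of scope.

## Intron loci

Introns are assigned to cross-species loci from two signals: proximity
of insertion sites (in intron-free coding coordinates) and conservation
of the 10-bp exonic flanks either side of the insertion point, with
flank conservation dominating. Concretely, two introns of the same host
gene link if their concatenated 20-mer flank identity (ungapped —
flanks are fixed-length snippets, alignment would add nothing) reaches
0.8, or reaches 0.7 while the sites differ by at most 30 nt;
single-linkage components are loci, and a component containing two
introns from one species is split at its weakest link until valid. The
30-nt window quantifies "neighboring positions", for which no number is
published; both cutoffs are exposed as arguments. Assignment is
deterministic and invariant to input order (records are canonically
sorted internally, and tie-breaks are lexicographic).

## Conservation statistics

`conservedIdentity()` is the proportion of alignment columns in which
every sequence carries the same non-gap residue, with the full
alignment length as denominator; columns containing any gap, including
all-gap columns, count as non-conserved — the conservative reading of
an unstated convention (alignments are assumed pre-trimmed). The
enrichment comparison of high-identity proteins between groups is an
exact one-sided hypergeometric tail, cross-checked in the tests against
direct enumeration. dN/dS values are ingested from externally computed
tables only, never estimated.

## The simulator and what passing tests mean

`simulateGenomes()` builds a root genome — the 35-gene complement in
the canonical seven-block order, intergenic regions of per-base GC 0.2
(so the genome lands near the 80% AT that characterises these genomes),
1–8 AT-rich ori elements, up to three free-standing ORFs, 30–60
GC-cluster insertions drawn from four consensus families, and a fifth
of intergenic regions laid down as near-pure-AT spacers — and evolves
it along an unrooted input tree: per-branch point substitutions
(0.01 per site per unit branch length), GC-cluster gain and loss, and
Poisson numbers of inversions and transpositions applied to the gene
order. Intron presence is sampled per leaf over 18 candidate loci in
*cox1* (10), *cob* (7) and *rnl* (1) at fixed coding offsets. Identical
seeds give byte-identical output.

Deliberate design choices, made once:

* AT spacers are whole intergenic regions of near-pure AT (GC 0.02),
  not low-GC islands inside 20%-GC filler: the fragment-level spacer
  definition (intergenic fragment minus clusters, >20 bp, GC < 0.1) can
  only ever recover spacers that fill their fragment, and in real
  genomes the spacer *is* the intergenic region.
* Cluster family consensus sequences have a GC-rich core whose every
  16-mer window carries two mutations of margin above the 0.75
  threshold, with short AT edges. This keeps a planted cluster
  detectable as one piece under point mutation and makes the detected
  extent match the planted extent despite the coverage rule's boundary
  creep.
* Insertions keep ≥ 20 bp clearance from existing elements so that
  distinct planted clusters are not fused by the <10 bp joining rule.
* Rearrangement arcs are uniform in start and length; event-size
  distributions are not modelled.
* Inversion:transposition intensity defaults are 1.0:1.5 per unit
  branch length, matching the observed dominance of transpositions.

What the simulator does **not** emulate: codon structure and selection
(no dN/dS truth), per-lineage architectural differences (all leaves
inherit one root architecture; real distant relatives have far fewer
clusters and smaller genomes), intron gain/loss along branches
(presence is i.i.d. per leaf), GC-cluster activity inside oris, and
replication-origin sequence motifs. Passing recovery tests therefore
demonstrates correctness of the detection and inference machinery under
the stated statistical model, not performance on real annotated
genomes.

## Numerical and validation choices

* The branch-rate recovery experiment (15 leaves, 20 markers, 25
  replicates) runs on the 15-taxon topology with **unit branch
  lengths** and three per-branch intensity tiers (0.02 / 0.35 / 1.2
  events per unit length — stable, intermediate and fast lineages, in
  the proportions inversion:transposition = 0.4:0.6). On trees with
  near-zero internal branches the per-branch *rate* (bsGOL divided by
  branch length) is noise-dominated for any estimator — almost no
  events occur on a branch of length 0.02 — so equal lengths isolate
  the solver property being tested: Spearman rank correlation between
  solved rates and true intensities, which lands at ~0.85–0.95 and is
  required to reach 0.8.
* Problem sizes in the test suite: the oracle equivalence runs 200
  random sequences up to 500 bp; detection scoring uses three of the
  fifteen simulated genomes (~170 kb of sequence); these sizes give
  stable statistics while keeping the default test run fast.
* `pracma::lsqnonneg` returns the unique NNLS solution for the
  full-column-rank design matrices that arise from binary trees; for
  rank-deficient unconstrained solves the Moore–Penrose pseudoinverse
  (minimum-norm solution) is used.
* Degenerate inputs: empty sequences yield empty cluster sets (not
  errors); alignments with zero columns, single-member loci, regression
  with fewer than three genomes or a constant predictor, and GOL values
  outside [0, 1] are rejected or flagged explicitly.

## Known limitations

The GenBank reader covers the flat-file subset this package writes and
typical organellar records (LOCUS/FEATURES/ORIGIN, `join`,
`complement`); it is not a general-purpose parser. Family grouping
quality depends on the unpublished cut height; with highly diverged
GC-rich sequences (an effectively two-letter alphabet) chance alignment
identity is high and families below ~60% identity cannot be separated
reliably. The DCJ distance is defined for equal marker sets on single
circular chromosomes only. The intergenic-variation regression
(`intergenicVariation()`) implements the line-regression reading of
"fraction of size variation explained" — the $R^2$ of genome size on
intergenic size; reproducing published figures for real genomes
requires the deposited accessions as input and is outside the test
suite's scope.
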