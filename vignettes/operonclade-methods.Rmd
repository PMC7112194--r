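---
title: "Methods: phylogenetic clustering and evolutionary classification of EPS operons"
author: "operonclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic clustering and evolutionary classification of EPS operons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonclade)
```

## The problem

Synthase-dependent exopolysaccharide (EPS) operons — cellulose, PNAG,
Pel, alginate, acetylated cellulose — are short runs of co-transcribed
loci anchored by a membrane polysaccharide synthase. Across bacteria the
same operon type appears with lost subunits, tandem and whole-operon
duplications, fused proteins, and shuffled locus orders, and the loci
themselves diverge into sub-families that track taxonomy and horizontal
transfer. `operonclade` classifies both levels: it clusters each locus
family on evolutionary distance and it reconstructs and classifies the
operons those loci form.

## Threshold clustering and the Q scores

For one locus family, the input is a patristic distance matrix: for
leaves $i, j$ of the family's tree, $d(i,j)$ is the sum of branch lengths
on the unique path between them, in expected amino-acid substitutions per
site. Distances are read from the tree with `ape` and do not depend on
root placement; trees may be multifurcating (consensus trees often are),
and zero-length branches are legal, so identical sequences may sit at
distance 0.

A cutoff $c$ is swept from 0 upward in steps of 0.01 substitutions/site
(both defaults changeable). At each $c$, sequences are merged by the
transitive closure of $d(i,j) < c$ — single linkage with a *strict*
inequality, so at $c = 0$ nothing clusters and once $c$ exceeds the
largest distance everything is one component. The sweep stops one step
past the maximum pairwise distance, where the partition is the single
all-in component.

Each partition is scored by three quantities:

* **Proportion clustered** $p$ — sequences in components of size ≥ 2
  divided by all sequences. Singleton components are reported as
  "unclustered"; counting them would make $p$ uninformative.
* **Mean silhouette** $\bar s$ — for each clustered sequence,
  $s(i) = (b(i) - a(i)) / \max(a(i), b(i))$ with $a(i)$ the mean distance
  to its own cluster and $b(i)$ the smallest mean distance to another
  cluster (size ≥ 2). If $a(i) = b(i) = 0$, $s(i) = 0$.
* **Dunn index** $DI$ — minimum inter-component distance over maximum
  cluster diameter.

The composites are $Q1 = \bar s + DI$, $Q2 = p + \bar s + DI$ and
$Q3 = p\,(\bar s + DI)$; the cutoff maximising the chosen scheme defines
the family's clustering. All three are exposed because they genuinely
differ: Q1 ignores coverage, Q3 rescales rather than adds it. Q2 is the
default.

### Why the Dunn index sees the complete partition

Threshold clustering partitions *every* sequence into a connected
component; "clusters" are merely the components of size ≥ 2. We evaluate
the Dunn index over the complete partition: singleton components
participate in the inter-component minimum $\delta$, while only proper
clusters contribute diameters to the denominator. The alternative —
ignoring singletons entirely — makes the sweep degenerate: because $DI$
enters the composites linearly and is typically an order of magnitude
larger than $p \le 1$, a partition that trims a boundary sequence into a
singleton almost always gains more $DI$ (a slightly smaller maximum
diameter) than it loses in $p$, so the optimum systematically sheds the
very sequences the clustering is supposed to place. With the complete
partition, a freshly trimmed singleton sits close to its former cluster,
$\delta$ collapses, and trimming is only rewarded when the sequence is
genuinely distant. The `dunnIndex()` documentation records the same
convention.

### Numerical conventions

* **Plateaus.** Two cutoffs yield the same partition iff no pairwise
  distance lies between them; the sweep evaluates each distinct partition
  once and shares its scores across the plateau. Results are identical to
  scoring every grid point, only cheaper.
* **Ties.** Equal scheme scores resolve to the smallest cutoff — the
  finest clustering — deterministically.
* **Degenerate partitions.** Fewer than two proper clusters leaves the
  metrics undefined; such cutoffs are flagged invalid and skipped by the
  arg-max (never scored 0), so the trivial single-cluster end state can
  never win. A matrix whose optimum is never valid (e.g. two sequences)
  raises a "no valid clustering" error.
* **All-duplicate clusters.** If every cluster has diameter 0 while the
  components are separated, $DI$ is taken against an epsilon floor of
  1e-9 and flagged, preserving the higher-is-better ordering.
* **Serialisation.** Distance matrices round-trip through a square TSV
  with 15 significant digits, so cutoff comparisons are stable across
  write/read.

## Clades and clade combinations

Clusters are ranked by the mean distance of their members to a designated
reference sequence (for cellulose, the *E. coli*-type bcsA, bcsB, bcsZ,
bcsC entries): the reference's own cluster is clade 1 by construction and
the rest take 2..m in ascending mean distance, ties broken toward the
larger cluster and then the lexicographically smallest member. Singletons
receive suffix codes S1, S2, … by distance to the reference so the clade
map is total. An operon is then labelled by the clade codes of its loci
in reference family order, e.g. `1:1:1:1` (all loci in the reference
clusters), `1:3:5:3` (divergent bcsB/bcsZ/bcsC lineages), or `1:1:1:-`
(pore lost); for a duplicated family the locus first in genomic order is
used.

## Operon reconstruction rules

Hits arrive as one row per (protein, family) with 1-based inclusive
coordinates (GenBank convention); a protein hit by two family models is a
candidate fusion and carries both rows. Three rules apply in order:

1. **Significance**: per-family E-value ≤ 1e-5, inclusive.
2. **Proximity prefilter**: a hit survives only if another hit of the
   same system sits on the same replicon within twice the reference
   operon span (nearest-boundary distance, any partner suffices). This
   runs before chaining; the intent is to discard stray singletons before
   they can seed chains.
3. **Chaining and composition**: loci sorted by start chain while the
   intergenic gap `start(next) − end(prev) − 1` is ≤ 5 kb (overlaps,
   i.e. negative gaps, always chain; negative gaps are reported as 0
   everywhere). A chain is an operon if it has ≥ 2 loci, a
   synthase-family locus, and a locus of another family — the companion
   family may be contributed by a fusion protein, in which case the call
   is flagged.

Strand is recorded but never breaks a chain; operons with internal strand
flips are real and are handled by the rearrangement logic instead. An
optional second hit table (from an iterative search round) can be merged;
its rows are flagged and treated identically by the rules.

## Event classification

Against the reference operon, five event types are called:

* **Loss** — one record per reference family with no hit in the operon.
  A family seen only inside a fusion protein is detected, not lost.
* **Locus duplication** — a family with ≥ 2 distinct loci in the operon
  whose nearest boundaries are < 10 kb apart; one record per family.
  (Within an operon the 5 kb chain gaps make the distance clause binding
  only when other genes intervene.)
* **Fusion** — one record per locus matching ≥ 2 family models.
* **Rearrangement** — loci are projected to their families in genomic
  order, the order is reversed when the majority strand is "−" (exact
  ties resolve to the synthase's strand), fusion loci expand to their
  families in reference order *after* that normalisation, duplicated
  families reduce to their first occurrence, and the result is compared
  with the reference order restricted to the families present. A loss
  alone therefore never doubles as a rearrangement, and the reference
  rendered as an operon (on either strand) is never rearranged.
* **Operon duplication** — one record per unordered pair of same-type
  operons of a genome at ≥ 10 kb (inclusive); different replicons always
  count. Counting is per pair, so three mutually distant copies yield
  three records.

## Genomic-proximity networks

One node per (family, clade) with the cluster's member count, a taxonomy
composition over the genomes contributing members (fractions sum to 1;
genomes without a taxonomy entry report "unknown"), a first-pass /
iterative discovery flag, and the family's rank in the canonical order
for vertical layout. Every same-genome pair of operon loci contributes
its nearest-boundary distance to the edge between their two nodes — pairs
beyond the operon scale included, since long-range (> 5 kb) edges between
same-genome operon copies are exactly the horizontal-transfer signal the
networks exist to expose. Cross-replicon pairs carry no defined distance
and create no edge. Edge distances average over all co-occurring locus
pairs (not per genome first), support counts distinct genomes, and the
display bins are < 100 bp, [100 bp, 5 kb] (both boundary values fall in
the middle bin), and > 5 kb. Exports: GraphML and SIF + attribute TSVs
for Cytoscape, JSON for lossless round-trips.

## Seed selection and dereplication

`selectSeeds` builds the non-redundant training set for an expanded HMM:
starting from the reference, it repeatedly takes the highest-scoring
match of the *last selected* sequence whose percent identity to *every*
already-selected sequence is below 97 %, until 20 sequences (default) or
exhaustion, which is recorded as a shortfall. Redundancy is enforced
against the whole selected set — the only reading that guarantees the
final set is pairwise non-redundant — and redundant candidates are
skipped in rank order rather than restarting from the reference. Ranking
uses the bit-score column when present, identity otherwise; ties break
lexicographically. `greedyDereplicate` is a desk-scale longest-first
representative picker at 90 % identity for collapsing near-identical
sequences before tree building; the member map is kept as metadata and
cluster counts are not re-inflated by it.

## What the simulator does and does not emulate

`simulateCladeTree` builds one random coalescent-shaped subtree per clade
(`ape::rcoal`), rescaled so all leaves sit `intraScale/2` below the clade
root, joins clade roots by `interScale/2` branches, and multiplies every
branch by log-normal noise (`noiseSd`, default 0 in construction, 0.1 in
the recovery studies). At zero noise every intra-clade distance is below
every inter-clade distance by construction. Defaults (3 clades × 5
leaves, intra 0.05, inter 1.0) give the 20:1 separation used throughout
the tests.

`simulateSurvey` plants one reference-derived operon per genome on a 5 Mb
synthetic replicon, mutating it independently per event type with the
probabilities in `eventMenu`; a whole-operon duplication adds a canonical
copy 20–50 kb downstream. Event targets are deterministic — loss removes
the last reference family (the outer-membrane-pore slot of bcsABZC),
duplication tandem-copies the synthase, fusion merges families 2 and 3,
rearrangement relocates family 2 (or the fused locus) — chosen so that
any combination of planted events remains exactly recoverable: no planted
event can mask or mimic another. Decoy hits are isolated singletons
placed at least twice the reference span from any operon and 40 kb from
each other, so the prefilter and the composition rule discard them by
construction.

The simulator emulates coordinates, scores and planted truth, not
biology: there are no evolved sequences, no gene prediction errors, no
draft-genome contig breaks, no partially significant hits near the
E-value threshold, and the trees are geometric stand-ins rather than
inferred phylogenies. Passing the planted-recovery tests therefore shows
the *rules* are implemented exactly as specified; it does not measure
sensitivity of the upstream homology searches on real genomes.

## Problem sizes and budgets

The test suite and the acceptance script use deliberately small problem
sizes chosen so the full battery runs in minutes on one core: metric
oracles on 200 random matrices of ≤ 12 sequences, patristic oracles on 50
random trees of ≤ 16 leaves, clade recovery on 100 simulated 15-leaf
trees, and operon/event recovery on a 200-genome survey with all five
event probabilities at 0.3 and 5 decoys per genome. The algorithms are
quadratic in family size at worst (silhouette, Dunn) and scale to the
hundreds-of-sequences families typical of single locus families without
special handling.

## Known limitations

* The cutoff sweep's grid (0.01) bounds how finely plateaus are resolved;
  partitions whose critical distances differ by less than the step are
  indistinguishable, which matches the method's definition but should be
  remembered when distances are very small.
* The prefilter runs before chaining; a variant order (chain first,
  prefilter after) is not implemented.
* "Size of the reference operon" is interpreted as its nucleotide span,
  not its locus count.
* Network edges require a shared replicon; co-occurrence across replicons
  is visible in operon-duplication events but not as network edges.
* Clade numbering depends on the chosen reference sequence; comparing
  clade combinations across runs requires the same reference labels.
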