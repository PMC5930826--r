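---
title: "Methods: pan/core genomes, AAI species delimitation, and recovery testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan/core genomes, AAI species delimitation, and recovery testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pancocci` re-implements, as a tested and reusable pipeline, the
comparative-genomics workflow used to characterize 29 cocci-shaped
*Sporosarcina* genomes: all-vs-all protein similarity, threshold-based
ortholog clustering into core / accessory / strain-specific gene sets,
ordered core-gene concatenation, average amino-acid identity (AAI) and
fragment-based average nucleotide identity (ANI) matrices, species
delimitation at 95% AAI, and distance trees built from core-gene,
gene-content and AAI signals. A seeded simulator of proteome families with
planted clade structure stands in for the sequenced strains, so every claim
the pipeline makes can be checked against a known truth.

## The similarity engine

All comparisons reduce to optimal Smith–Waterman local alignment with
affine gaps, computed by a small C++ kernel. The default protein scoring is
BLOSUM62 with gap open −11 and gap extend −1 — the canonical parameter set
for gapped protein search — with Karlin–Altschul statistics
(λ = 0.267, K = 0.041) turning raw scores into bit scores and E-values:

* bit score `b = (λ·S − ln K) / ln 2`,
* E-value `E = m·n·2^(−b)` with `m` the query length and `n` the total
  residue count of the search database (all proteomes combined, as for a
  single BLAST database).

From each best alignment the pipeline derives the two statistics the
clustering cutoffs are expressed in:

* **PI** (percent identity) = 100 × identical aligned pairs / alignment
  columns (gaps included in the denominator, matching the `pident`
  convention), and
* **PC** (percent query coverage) = 100 × aligned query span / query
  length (the `qcovs` convention).

Tie-breaking is deterministic: the DP prefers diagonal over up over left
moves, and among equal-scoring end points the first reached in row-major
order. A pair with no positive-scoring residue pair yields an explicit
empty-alignment sentinel rather than a degenerate hit.

Because aligning every cross-genome gene pair is wasteful, the all-vs-all
search first builds a k-mer inverted index and only aligns pairs sharing at
least one exact word. The single-pair `kmer_prefilter()` default is k = 4;
the family-scale pipeline drivers (`run_pancore()`, `run_species()`) use
k = 5, which at the divergences of interest is lossless in practice — at
75% identity two 120-residue orthologs share dozens of 5-mers — while
cutting the alignment load roughly twentyfold. The prefilter's safety
property (a pair rejected by the filter does not qualify at the permissive
clustering cutoffs) is checked empirically in the test suite.

## Ortholog clustering and pan/core accounting

Hits are filtered by a threshold set (PI, PC, E-value ceiling); an
undirected edge joins two genes when at least one direction passes
(a configuration switch demands both). Thresholds are inclusive (≥ / ≤):
boundary ties are measure-zero on real data, and inclusive bounds are
simpler to reason about. Two canonical threshold sets are shipped:

* **core**: PI ≥ 90, PC ≥ 90, E ≤ 1e−4 — the strict setting under which
  the 29-strain study recovered 221 core genes;
* **pan**: PI ≥ 30, PC ≥ 70 — the permissive setting that produced the
  8610-cluster pan-genome.

Clusters are single-linkage connected components of the edge graph; genes
with no qualifying edge become singletons, so clusters always partition the
gene universe. This is the simplest rule consistent with a
presence/absence-oriented parser; its known chaining risk is documented
rather than patched with heavier machinery (MCL, RBH triangles), and an
independent transitive-closure oracle checks the implementation on random
graphs. A cluster is **core** when every genome has at least one member,
**strain-specific** when all members come from one genome; the
**pan-genome size** is the total cluster count including singletons (the
only reading under which strain-specific genes are clusters). Paralogs are
allowed; the representative of a cluster in a genome is its longest member
(ties broken by gene id), and core representatives are concatenated in
ascending cluster-id order — the same order in every genome — to form the
supermatrix sequences.

## AAI, ANI and species delimitation

AAI between two proteomes is the unweighted mean PI over reciprocal best
hit (RBH) pairs, where both directions must pass PI ≥ 30 and PC ≥ 70. The
web calculator used in the original study does not publish its defaults;
these RBH filters are the conventional ones and are recorded in every run
report so results are auditable. A pair with no qualifying RBH has an
*undefined* AAI, propagated as `NA` (never 0) and treated as below any
cutoff downstream.

ANI follows the classic fragment convention: the query genome is chopped
into consecutive 1020-bp windows, each window is aligned to the subject on
both strands (match +1, mismatch −2, gap open −5, extend −2), and windows
whose best hit passes PI ≥ 30 and coverage ≥ 70 contribute their identity.
Both directions are averaged so the matrix is symmetric.

Clades (candidate species) are the single-linkage components of the graph
joining strains at ≥ 95% identity, the conspecificity threshold for AAI.
Every partition carries an `is_clean` audit: `TRUE` iff all within-clade
pairs sit at or above the cutoff and all between-clade pairs below it — in
which case the partition is linkage-independent. When the audit fails the
partition is flagged rather than silently resolved.

## Trees and the concordance question

The study's headline qualitative claim is that core genes, accessory gene
content and identity all delimit the same eight clades. To test that claim
without external alignment and ML tools, the package builds three distance
matrices and runs Saitou–Nei neighbor joining (via `ape::nj`, negative
branches clamped to 0) on each:

1. **core**: 100 − length-weighted mean PI over core-cluster
   representatives, pairwise between strains;
2. **accessory / gene content**: Jaccard distance over presence/absence
   profiles;
3. **identity**: 100 − AAI.

`run_species()` then cuts each tree into as many groups as the AAI
partition has clades (single-linkage on the tree's cophenetic distances)
and reports whether all three tree partitions equal the AAI partition.

One design choice deserves emphasis. The presence/absence profile fed to
the accessory tree comes from the *strict* (core-threshold) clustering,
not the permissive one. At 90% identity, orthologs collapse only within
near-identical groups, so the strict clusters are sequence *variants*;
which variant a strain carries is exactly the clade-level signal an
accessory analysis needs. Under the shipped simulator this choice is not
optional: the generator plants core genes and strain-private genes but no
clade-shared accessory genes, so the permissive clustering gives every
strain an identical shared profile plus private singletons — the Jaccard
distance is then the same constant for every pair of strains and carries
no signal at all, while the strict clustering resolves each core family
into per-clade variant clusters and recovers the planted structure.
Similarly, the shared-gene families used for the core tree are taken from
the strict run when it has universal clusters and from the permissive run
otherwise (at the simulator's between-clade divergence, ~76% expected
identity, no cluster can span all strains at the 90% cutoff — the
permissive run is the one that sees the planted core).

## The simulator and its guarantees

`simulate_family()` emulates the study system. Its defaults are the
simulated study conditions: 29 strains in 8 clades with clade sizes
(3, 1, 3, 5, 2, 5, 5, 5) following the published clade rosters, a planted
core of 200 genes, 50 strain-specific genes per strain, substitution
probability 0.01 per site from clade root to strain and 0.12 from ancestor
to clade root, and gene lengths uniform on [60, 180] (mean 120 — reduced
from realistic protein lengths to keep the quadratic alignment work
proportionate; lengths are bounded and mean-preserving by construction).
Sequences are drawn from the Robinson–Robinson background composition;
substitution replaces a site with a *different* residue drawn from the
background, so expected identity to the parent is exactly 100·(1 − q).
With two independent substitution layers, expected identity is
100·(1 − q_w)² within clades and 100·[(1 − q_w)(1 − q_b)]² between —
98.0% and 75.9% at the default rates, far either side of the 95% species
cutoff. An indel mode exists (rare geometric-length insertions/deletions)
but is off by default so these closed forms stay exact.

The recovery tests assert *exact* equality between recovered and planted
core/pan counts, which requires that planted families can never merge in
the clustering. Unrelated random proteins of this length occasionally
produce chance local alignments that pass PI ≥ 30 with 70% coverage —
rare per pair, but a 1650-gene family has over a million cross-family
pairs — and substitution can create such similarity between copies even
when the ancestors show none. The generator therefore enforces
unmergeability in three layers:

1. at draw time, a candidate gene is rejected if its best alignment to any
   already-planted gene approaches the clustering cutoffs (margins
   PI 25 / coverage 60 for core–core pairs, 27/65 for core–specific,
   exact 30/70 for specific–specific, which never mutate);
2. strain-specific genes share no 6-mer with any ancestral core gene;
3. after the strains are derived, the realized copies are scanned for
   cross-family pairs qualifying at PI ≥ 30 with ≥ 70% coverage of either
   copy (candidates = pairs sharing a 5-mer, matching the search
   prefilter), and any affected family is redrawn until none remain.

The third layer is the binding guarantee; the first two just keep the
redraw rate low. Everything is drawn under a single seed, so families are
byte-reproducible, and redraws are part of the same deterministic stream.

What the simulator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data — includes: indel-rich
divergence and alignment-length heterogeneity, clade-shared accessory
genes and horizontal transfer, paralog families, composition bias across
lineages, and annotation noise (fragmented or chimeric gene calls). The
recovery results validate the pipeline's logic (graph construction,
clustering, RBH averaging, delimitation, tree cutting), not the biological
fidelity of any particular threshold.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally and in exported
  hit tables.
* Identity matrices force a 100 diagonal and symmetry; distance matrices a
  zero diagonal.
* Undefined AAI/ANI is `NA`, never 0; `delimit_clades()` treats `NA` as
  below cutoff; `run_species()` warns and substitutes the maximal observed
  distance before tree building.
* Matrices are serialized at 4 decimal places; round-trips are exact to
  1e−4.
* `nj_tree()` clamps negative NJ branch lengths to zero with a message;
  path distances on additive inputs are reproduced to 1e−9 before
  clamping.
* Empty proteomes in the presence screen produce an all-absent report with
  a warning; empty sequences and duplicate ids are hard errors naming the
  offender.

## Problem sizes used by the shipped checks

The acceptance script and the recovery tests run the study-mirroring
configuration (29 strains × 250 genes, mean length 120) over five seeds,
which keeps a full five-seed recovery under ten minutes on a single CPU at
roughly 300 000 alignments per family. The oracle-equivalence checks use
hundreds of random pairs at lengths 10–60, where an independent
implementation (Biostrings' pairwise aligner) is fast enough to serve as
the reference. ANI checks use 4-kb genomes so each window-by-genome
alignment stays small.

## Command-line-free by design

The package is an analysis library: the exported functions
(`simulate_family()`, `run_pancore()`, `run_species()`, `compute_ani()`,
`gene_presence_screen()`, `summarize_genome_table()`) plus this vignette
are the interface a user drives from R or Rscript; every pipeline artifact
(cluster tables, matrices, Newick trees, JSON reports) is written by the
`out_dir` arguments of the two `run_*` drivers.
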