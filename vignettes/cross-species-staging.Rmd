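---
title: "Cross-species metaexon construction and developmental staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species metaexon construction and developmental staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthostage)
```

## The problem

Placing cultured human pluripotent stem cells — or any query population —
on the developmental axis of a primate embryo requires comparing
single-cell expression profiles across two species measured with two
different protocols. Two obstacles stand in the way. First, the two
genomes are annotated independently, so expression must be quantified over
features that are demonstrably one-to-one orthologous; a gene-level
comparison over naive annotation matches is contaminated by paralogs,
mis-assembled loci and isoform differences. Second, the two platforms
(here emulated as a UMI-based protocol for the query species and a non-UMI
protocol for the reference embryo) distort expression in ways that dwarf
the biology, so the two matrices must be made comparable before any joint
embedding.

`orthostage` implements both halves as a reusable, tested pipeline:

1. **Orthologous metaexon construction** — from exon annotations and
   exon-versus-genome alignment hits, retain exons with a confident,
   unique, reciprocal cross-species placement, and collapse isoform
   variants into per-gene *metaexons*, the cross-species quantification
   unit.
2. **Harmonized joint staging** — quantify, QC-filter and normalize both
   matrices, reduce every cell to the *ranks* of its gene expression
   (z-scored), run PCA on the merged data, and assign each query cell to
   the nearest reference stage in a selected component subspace.

## The orthology filter chain

Exons of the source species (A) are aligned against both genomes. An exon
survives iff:

* its best hit in genome B has identity **≥ 0.92** (inclusive: "at least");
* its best self-genome hit *maps back* to its own annotated locus
  (overlap ≥ 1 bp, same strand) — the reciprocal criterion;
* it has **no second match with identity > 0.90** (strict) in *either*
  genome — the guard against paralogs and segmental duplications. The
  second match in genome A is the rank-2 self-hit (rank 1 being the
  annotated locus itself); in genome B it is the rank-2 cross-hit.

A subtlety in the reciprocal criterion: an exact duplication produces two
self-hits tied at identity 1.0, and which of them ranks first is a
tie-break artifact. We therefore let the criterion pass when *any*
maximal-identity self-hit overlaps the annotated locus, so exact
duplications are attributed to the second-hit rule — the filter that
exists for them — rather than to an accidental ordering of equal hits.

Surviving exons are collapsed per gene: overlapping **or bookended**
intervals merge (bookended intervals encode contiguous exonic sequence),
disjoint intervals stay separate metaexons. Collapse is implemented with
`IRanges::reduce()` and is checked in the tests against an independent
brute-force merge-until-fixpoint oracle on hundreds of random instances.

Gene-level filters then remove: metaexons overlapping annotated exons of a
second gene (in either species); all metaexons of genes annotated on two
or more chromosomes in either species; and metaexons whose intron to the
adjacent retained metaexon differs in length between species by
**≥ 10,000 bp** (inclusive), a signature of assembly or annotation error.
The intron rule is evaluated per adjacent pair in a single 5'→3' pass:
when a pair fails, the downstream member is removed and the kept member is
compared with the next. The annotation text underdetermines whether the
flanking intron is the upstream or downstream one; comparing each
*adjacent retained pair* covers both readings and is the weakest rule
consistent with a per-exon phrasing. Every removal carries a reason code
(`low_identity`, `no_reciprocal`, `second_hit`, `multi_gene`,
`multi_chrom`, `intron_diff`, `unannotated`) and each filter stage
reports `input = retained + removed`.

### The built-in aligner

At desk scale the exon-versus-genome hits are produced by a k-mer-seeded
ungapped-extension aligner (`compute_exon_hits()`): exact 11-mer seeds,
full-query extension along each seed diagonal, identity = matching bases /
aligned columns, both query orientations. Gaps are not modeled; at the
simulator's substitution-only divergence they cannot occur, and for real
genome-scale work the package instead ingests external BLAT output
(`read_psl()`), where identity is computed as
`matches / (matches + misMatches + qNumInsert + tNumInsert)` so gapped
alignments are penalized per gap opening. Hits are ranked per query by
identity, then alignment length, then leftmost coordinate — a total order,
so results are reproducible.

## QC and normalization

Cell-level QC retains a cell iff its total counts lie in
**[12,500, 60,000]** and it detects **≥ 4,500** genes (count > 0). The
boundary readings are: "fewer than 12,500" removed (12,500 kept), "more
than 60,000" removed (60,000 kept), "<4,500 genes" removed (4,500 kept).
Published descriptions of this filter set sometimes omit the lower counts
bound; `qc_config(min_total_counts = NA)` reproduces that two-rule
variant, and the three-rule superset is the default.

Expression is normalized as `log2(1 + CPM)` computed on the full
pre-gene-filter matrix. Gene-level filtering is per *phenotype group* (a
sorting fraction, or an embryo stage): a gene is retained iff in at least
one group the fraction of cells expressing it **strictly above** the
cutoff is **at least 10%**. The cutoff is platform-dependent — 1
log2(CPM+1) for the non-UMI reference, 5 for the UMI query data, matching
the very different count depth distributions of the two protocols. "Above
a cutoff" is read as strict; both boundary directions are covered by
tests, and the choice only shifts the retained set at exact-cutoff values,
which have measure zero in real data. A raw-count analogue
(`filter_genes_min_count()`, ≥ 1 count in ≥ 10% of a condition group)
serves the single-species path. Downstream analysis is limited to the
deterministic sorted intersection of the two species' retained sets
(`common_genes()`), optionally translated through an ortholog table.

Filter order is fixed: cells first, then genes, so detection fractions are
computed on QC-passing cells. Relaxing any threshold can only grow the
retained sets — a monotonicity property the tests assert on random
matrices.

## Rank harmonization

Within each cell, genes are ranked ascending by abundance; ties all take
the **minimum** rank of their tie group (so `[0, 3, 3, 7]` becomes
`[1, 2, 2, 4]`, and zeros form one large bottom tie group — no special
dropout handling). Ranks are then z-scored per cell (sample sd, n−1;
population sd would differ only by a constant factor, which PCA subspaces
ignore). Each non-degenerate cell row therefore has mean 0 and unit sd;
constant cells are emitted as zero rows and flagged.

The transform's defining property: any *strictly monotone* per-cell
distortion of expression — platform saturation, amplification
nonlinearity, any `x^γ` — leaves the output **bit-identical**. That is the
pipeline's central testable premise and is asserted directly (cube,
exponential and affine transforms). The rank direction (lowest = 1) is a
convention; flipping it negates every z-row, which changes no PCA
subspace. Ranking operates on the common-gene submatrix, since downstream
analysis is defined on the common genes; ranking before subsetting is
available but changes relative ranks only through the dropped columns.

## Joint PCA and stage assignment

The two harmonized matrices are row-concatenated (dataset A, then B) and
decomposed with `stats::prcomp` — full deterministic SVD, centering only
(rows are already rank-z-scored, so per-gene unit-variance scaling is
off by default). Component signs are fixed by making each component's
largest-magnitude loading positive. Variance fractions are reported
relative to total variance, the screeplot quantity.

With a dominant platform offset, PC1 absorbs the species/batch axis, and
developmental structure appears on the next components: PC2 resolving the
pre/post-implantation axis and PC3 the post-implantation progression in
the motivating analysis. The original analysis read developmental position
off these plots *visually*; to make the pipeline testable we quantify it:
`assign_stage()` assigns each query cell to the stage with the nearest
reference centroid in the selected subspace (default PCs 2–3), or by
k-nearest-neighbor majority vote (`k = 15`). Ties are broken by smaller
mean distance, then by earliest developmental stage, and flagged. PCA is
run on all merged cells jointly; a projection variant (fit on the
reference, project the query) is deliberately out of scope here since the
merged fit is what the motivating analysis used.

## Stage-specific panels

No formula for the original stage-marker selection is available, so the
package uses a transparent rule: a gene enters the panel for stage set S
iff its mean log-expression in S exceeds the complement mean by
**≥ 1 log2 unit** (configurable) and it is detected in **≥ 50%** of S
cells. Stage sets can be single stages or unions (e.g. all-epiblast),
mirroring how marker rows are organized in embryo-reference summaries, and
externally curated panels can be supplied as a two-column TSV instead.
Panel scores (per-cell mean over panel genes) are summarized per cell
group as median, quartiles and extremes — the data behind violin-style
figures.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every end-to-end claim in the test suite is evaluated.

**Genomes** (`generate_genomes()`): 50 genes of 2–4 exons (90–150 bp,
introns 200–400 bp) on one chromosome per species. Species B exons are
copies of A's mutated at a 2% substitution rate (so cross-identities
concentrate near 0.98, comfortably above the 0.92 floor); 10 exons
additionally get an exact duplicate planted elsewhere (alternating host
genome) — the second-hit scenario; 5 genes get their first intron
lengthened by 12,000 bp in B — the intron-size scenario. The truth table
records the expected fate of every exon, including that all exons
*downstream* of a shifted intron fall to the single-pass intron rule. Note
that at 10% divergence the identity of a 90–150 bp exon is a binomial
average with sd ≈ 0.03, so a sizeable minority of exons still clears the
0.92 floor by chance; "divergence well below the floor removes nearly
everything" is only true for longer exons.

**Counts** (`simulate_counts()`): 2 species × 5 stages × 40 cells × 2,000
genes, minutes on one CPU. Gene programs are shared across species:
log-normal baselines; 20% of genes carry a *trajectory* profile (log2 mean
linear in normalized stage time, slope sign random) so the data have a
genuinely one-dimensional developmental axis a single PC can order; 15%
are *stage-specific markers* (+1.5 log2 in exactly one stage), the
panel-derivation target. Both classes are needed: trajectory genes alone
give nothing for single-stage panels to find, and marker blocks alone give
unordered clusters that no single PC orders monotonically.

The species effect has three parts, chosen to emulate a UMI versus non-UMI
protocol pair: a monotone distortion `x^γ` (γ_B = 1.6) that rank
harmonization must nullify *exactly*; a fixed **gene-wise capture bias**
(2^N(0, 1.5) per gene in species B) emulating protocol-specific per-gene
efficiencies (3'-bias, length bias) — constant across cells, hence
untouched by within-cell ranking, and the component that dominates PC1;
and mild stochastic asymmetries (dropout 0.15 vs 0.10, negative-binomial
dispersion 0.3 vs 0.6, log-normal library sizes around 30,000). The
capture bias is drawn independently of the stage program, so in a
2,000-gene space it is almost orthogonal to the developmental axis — the
geometry the joint-PCA design assumes. We deliberately do *not* use a
strong dropout asymmetry as the species effect: random zeroing is a
non-monotone distortion that attenuates the query species' stage signal on
exactly the components used for staging, i.e. it breaks the method itself
rather than testing it; the mild asymmetry retained here is enough to make
zero-structure differences visible without overwhelming the biology.

Under these defaults the pipeline separates species on PC1 with
non-overlapping scores, orders stages on PC2 with Spearman |ρ| ≈ 0.98, and
assigns ≥ 95% of query cells to their true stage; with the stage effect
set to 0 assignment collapses to chance (20% for 5 stages). Panel
derivation at this noise level recovers most but not all planted markers
(recall and precision in the 80–90% range; exact recovery holds on
noise-free profiles, which the tests also assert).

What the generator does **not** emulate: doublets, ambient RNA,
mitochondrial stress signatures, isoform switching, cell-cycle structure,
nonlinear (branching) trajectories, and any sequence-level read noise.
Passing tests therefore demonstrate the pipeline's correctness and its
robustness to monotone platform distortion plus gene-wise capture bias —
not robustness to every artifact of real single-cell data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF is read/written
  1-based closed via `rtracklayer`, BED written 0-based half-open.
* Hit ties: identity, then longer alignment, then leftmost target
  coordinate; all orderings in the package are total, so outputs are
  deterministic for a fixed seed.
* Reads overlapping features of two genes are discarded as ambiguous;
  within one gene the largest overlap wins (leftmost on ties), so
  gene-level counts equal the sum of metaexon-level counts by
  construction.
* Cells with zero totals are an error in `log2_cpm()` (they should have
  been removed by QC); constant cells z-score to zero rows with a flag;
  stages with no reference cells are excluded from assignment with a
  warning; empty matrices and empty metaexon tables round-trip as
  header-only files.
* Simulation scale (50 genes / 2,000 genes × 400 cells) keeps the full
  suite in tens of seconds on one CPU while leaving every statistical
  property (identity distributions, PC structure, recovery rates) far
  from small-sample degeneracy.

## Limitations

The aligner is substitution-only and sized for toy genomes — real
genome-scale runs should ingest BLAT PSL. The staging rule quantifies what
was originally a visual judgment; centroid assignment in a 2-PC subspace
is the simplest defensible rule, not the most powerful. Panel derivation
is a stand-in for an unspecified differential-expression procedure and is
best used with externally curated panels when available. Only two species
and a single reference stage axis are supported.
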