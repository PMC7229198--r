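# orthostage

Cross-species orthologous-metaexon construction and developmental staging
of single-cell transcriptomes.

## What problem this solves

Deciding where a cultured human pluripotent stem cell population sits on
the primate embryo's developmental axis means comparing single-cell
expression across two species measured with two different protocols.
`orthostage` provides the two computational halves of that comparison as a
tested R pipeline, for anyone integrating expression data across a species
pair:

1. **Orthologous metaexons.** From exon annotations (GTF) and
   exon-versus-genome alignment hits (built-in k-mer aligner for
   desk-scale genomes, or BLAT PSL ingestion), exons are kept iff the best
   cross-species hit has identity ≥ 0.92, the best self-genome hit maps
   back to the annotated locus, and no second match exceeds identity 0.90
   in either genome (paralog/duplication guard). Survivors are collapsed
   per gene into *metaexons* (overlapping/bookended intervals merged),
   then gene-level filters remove multi-gene overlaps, genes on ≥ 2
   chromosomes in either species, and metaexons whose adjacent intron
   differs in length by ≥ 10,000 bp between the species. Every removal is
   audited with a reason code.

2. **Harmonized joint staging.** Count matrices pass cell QC
   (12,500–60,000 total counts, ≥ 4,500 detected genes; boundaries
   inclusive as stated), log2(CPM+1) normalization and per-phenotype gene
   filtering (expression above a cutoff — 1 for non-UMI, 5 for UMI data —
   in ≥ 10% of some group's cells). On the common gene set, every cell is
   reduced to the z-scored **ranks** of its gene expression (ties take the
   minimum rank), which nullifies any strictly monotone platform
   distortion exactly. PCA on the merged matrix (`prcomp`, centering only)
   isolates the residual species/batch offset on PC1 and the developmental
   axis on the next components; each query cell is then assigned to the
   nearest reference-stage centroid (or knn majority) in a chosen PC
   subspace, by default PCs 2–3.

A seeded synthetic-data generator (toy genome pairs with planted
orthologs, exact-duplicate decoys and intron-size shifts; stage-structured
two-species counts with monotone distortion, gene-wise capture bias,
library-size variation, dropout and negative-binomial noise) exercises the
whole pipeline against known truth. See the vignette
(`vignettes/cross-species-staging.Rmd`) for the model, parameter meanings
and design rationale.

## Worked example

Build a metaexon table from a simulated genome pair (2% ortholog
divergence, 10 decoy duplications, 5 intron-shifted genes):

```r
library(orthostage)
sim   <- generate_genomes(genome_sim_config(seed = 1))
built <- build_metaexon_table(sim)
built$exon_report
#> Filter stage 'exon_orthology': 145 in, 135 retained
#>           stage     reason n_removed
#>  exon_orthology second_hit        10
built$gene_report
#> Filter stage 'gene_level': 135 in, 127 retained
#>       stage      reason n_removed
#>  gene_level intron_diff         8
head(built$metaexons[, c("metaexon_id", "gene_id", "start", "end",
                         "b_start", "b_end")], 3)
#>   metaexon_id gene_id start  end b_start b_end
#> 1  gene001.m1 gene001   300  440     300   440
#> 2  gene002.m1 gene002  1267 1409   13267 13409
#> 3  gene003.m1 gene003  3096 3210   27096 27210
```

All 10 planted duplications fall to the second-hit rule and all 8 exons
downstream of a shifted intron to the intron-size rule; the 127 clean
planted orthologs all survive, with paired coordinates in both genomes
(gene002's B coordinates show its 12 kb intron shift upstream).

Stage query cells against a labeled reference across a simulated
platform gap (γ_B = 1.6 monotone distortion, gene-wise capture bias,
protocol-specific noise):

```r
cs  <- simulate_counts(expression_sim_config(seed = 2))
res <- stage_cross_species(cs$A, cs$B, reference = "B",
                           stage_levels = cs$config$stages)
res$pca
#> pca_result: 400 cells, k = 10; variance fractions: 0.066 0.021 0.007 0.007 0.006 ...
head(res$assignments[, 1:3], 4)
#>      cell_id assigned_stage   tie
#> 1 A_ICM_c001            ICM FALSE
#> 2 A_ICM_c002            ICM FALSE
#> 3 A_ICM_c003            ICM FALSE
#> 4 A_ICM_c004            ICM FALSE

truth <- cs$A$cell_meta$phenotype[match(res$assignments$cell_id,
                                        cs$A$cell_meta$cell_id)]
mean(res$assignments$assigned_stage == truth)
#> [1] 0.96
```

PC1 (6.6% of variance) is the species/platform axis — the two datasets'
scores do not overlap on it — and PC2 orders the five developmental
stages; assigning each species-A cell to the nearest species-B stage
centroid on PCs 2–3 recovers the true stage for 96% of cells here.

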