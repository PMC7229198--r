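test_that("genome simulation is deterministic under a fixed seed", {
  cfg <- genome_sim_config(n_genes = 10L, n_decoy_duplicates = 2L,
                           n_intron_shift_genes = 1L, seed = 77)
  s1 <- generate_genomes(cfg)
  s2 <- generate_genomes(cfg)
  expect_identical(as.character(s1$genome_a), as.character(s2$genome_a))
  expect_identical(as.character(s1$genome_b), as.character(s2$genome_b))
  expect_identical(s1$exons_a, s2$exons_a)
  expect_identical(s1$truth, s2$truth)
  # annotated coordinates slice out the planted exon sequences
  seqs <- exon_sequences(s1$exons_a, s1$genome_a)
  expect_equal(unname(Biostrings::width(seqs)),
               s1$exons_a$end - s1$exons_a$start)
})

test_that("species B exons diverge at the configured rate", {
  cfg <- genome_sim_config(n_genes = 20L, ortholog_divergence = 0.05,
                           n_decoy_duplicates = 0L,
                           n_intron_shift_genes = 0L, seed = 78)
  sim <- generate_genomes(cfg)
  seq_a <- exon_sequences(sim$exons_a, sim$genome_a)
  seq_b <- exon_sequences(sim$exons_b, sim$genome_b)
  ident <- mapply(function(a, b) hamming_identity(as.character(a),
                                                  as.character(b)),
                  as.list(seq_a), as.list(seq_b))
  expect_equal(mean(1 - ident), 0.05, tolerance = 0.3)
  expect_lt(mean(ident), 0.99)
})

test_that("noise-free orthologs are fully retained; planted faults are caught", {
  sim <- generate_genomes(genome_sim_config(
    n_genes = 15L, ortholog_divergence = 0, n_decoy_duplicates = 3L,
    n_intron_shift_genes = 2L, seed = 79))
  res <- build_metaexon_table(sim)
  survivors <- unlist(strsplit(res$metaexons$constituent_exons, ","))
  clean <- sim$truth$exon_id[sim$truth$category == "clean"]
  expect_setequal(survivors, clean)                  # 100% clean retention
  reasons <- attr(res$exon_report, "reasons")
  names(reasons) <- sim$exons_a$exon_id
  decoys <- sim$truth$exon_id[sim$truth$category == "decoy"]
  expect_true(all(reasons[decoys] == "second_hit"))
})

test_that("count simulation is deterministic and carries truthful metadata", {
  cfg <- small_expr_config(seed = 80)
  c1 <- simulate_counts(cfg)
  c2 <- simulate_counts(cfg)
  expect_identical(c1$A$counts, c2$A$counts)
  expect_identical(c1$B$counts, c2$B$counts)
  for (sp in c("A", "B")) {
    cm <- c1[[sp]]
    expect_equal(nrow(cm$counts),
                 length(cfg$stages) * cfg$cells_per_stage)
    expect_equal(unique(cm$cell_meta$species), sp)
    expect_equal(as.vector(table(cm$cell_meta$phenotype)[cfg$stages]),
                 rep(cfg$cells_per_stage, length(cfg$stages)))
  }
  expect_equal(nrow(c1$truth$genes), cfg$n_genes)
  expect_equal(sum(c1$truth$genes$class == "stage_marker"),
               round(cfg$stage_marker_fraction * cfg$n_genes))
})

test_that("matched cells harmonize identically when species effects are off", {
  cfg <- small_expr_config(
    seed = 81, deterministic = TRUE,
    species_gamma = c(A = 1, B = 1),
    species_gene_bias_log2sd = c(A = 0, B = 0),
    dropout_rate = c(A = 0, B = 0), dispersion = c(A = 0, B = 0),
    library_size_sdlog = c(A = 0, B = 0))
  cs <- simulate_counts(cfg)
  ha <- zscore_cells(rank_cells(log2_cpm(cs$A)), dataset = "A")
  hb <- zscore_cells(rank_cells(log2_cpm(cs$B)), dataset = "B")
  expect_equal(unname(ha$values), unname(hb$values))
})

test_that("a monotone distortion alone is nullified by harmonization", {
  # gamma != 1 with no sampling noise: counts differ, harmonized ranks agree
  # wherever rounding does not create or break ties, so rank vectors of
  # matched cells correlate essentially perfectly
  base <- small_expr_config(
    seed = 82, deterministic = TRUE,
    species_gamma = c(A = 1, B = 1.6),
    species_gene_bias_log2sd = c(A = 0, B = 0),
    dropout_rate = c(A = 0, B = 0), dispersion = c(A = 0, B = 0),
    library_size_sdlog = c(A = 0, B = 0))
  cs <- simulate_counts(base)
  expect_false(identical(cs$A$counts, cs$B$counts))
  ra <- rank_cells(log2_cpm(cs$A))
  rb <- rank_cells(log2_cpm(cs$B))
  cors <- vapply(seq_len(nrow(ra)), function(i)
    cor(ra[i, ], rb[i, ]), numeric(1))
  expect_true(all(cors > 0.99))
})

test_that("the fixture suite regenerates byte-identically and matches truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gcfg <- genome_sim_config(n_genes = 8L, n_decoy_duplicates = 2L,
                            n_intron_shift_genes = 1L)
  ecfg <- small_expr_config()
  make_fixture_suite(d1, seed = 5, genome_config = gcfg,
                     expression_config = ecfg)
  make_fixture_suite(d2, seed = 5, genome_config = gcfg,
                     expression_config = ecfg)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 8)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  # written matrices reload and agree with an in-memory regeneration
  ecfg$seed <- 5L
  cs <- simulate_counts(ecfg)
  back <- read_matrix(file.path(d1, "counts_A"), format = "TSV")
  expect_equal(back$counts, cs$A$counts)
  expect_equal(back$cell_meta$phenotype, cs$A$cell_meta$phenotype)
  # GTF round-trips through the annotation reader
  exons <- read_exon_gtf(file.path(d1, "speciesA.gtf"), species = "A")
  gcfg$seed <- 5L
  gsim <- generate_genomes(gcfg)
  expect_equal(exons$start, gsim$exons_a$start)
  expect_equal(exons$end, gsim$exons_a$end)
  expect_setequal(exons$gene_id, gsim$exons_a$gene_id)
})

test_that("infeasible genome configs are rejected", {
  expect_error(genome_sim_config(n_genes = 4L, n_decoy_duplicates = 3L,
                                 n_intron_shift_genes = 2L),
               "n_decoy")
  expect_error(genome_sim_config(ortholog_divergence = 1.2), "divergence")
})
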