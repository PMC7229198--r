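# one annotated exon with configurable cross/self hit identities
one_exon <- function() {
  exon_records("e1", "g1", "chrA1", 1000L, 1100L, "+", species = "A")
}
self_hits_ok <- function(second = NULL) {
  h <- hit_row("e1", "chrA1", 1000, 1100, 1.0)
  if (!is.null(second))
    h <- rbind(h, hit_row("e1", "chrA1", 5000, 5100, second))
  rank_hits(h)
}
cross_hits <- function(best, second = NULL) {
  h <- hit_row("e1", "chrB1", 2000, 2100, best)
  if (!is.null(second))
    h <- rbind(h, hit_row("e1", "chrB1", 8000, 8100, second))
  rank_hits(h)
}

test_that("cross-species identity floor is inclusive at 0.92", {
  for (case in list(list(id = 0.95, kept = TRUE),
                    list(id = 0.92, kept = TRUE),     # "at least 92%"
                    list(id = 0.9199, kept = FALSE),
                    list(id = 0.91, kept = FALSE))) {
    res <- filter_orthologous_exons(one_exon(), cross_hits(case$id),
                                    self_hits_ok())
    expect_equal(nrow(res$retained) == 1L, case$kept, info = case$id)
    if (!case$kept)
      expect_equal(attr(res$report, "reasons"), "low_identity")
  }
})

test_that("second-hit exclusion is strict above 0.90, in either genome", {
  # clearly below: kept
  res <- filter_orthologous_exons(one_exon(), cross_hits(0.95, 0.85),
                                  self_hits_ok(0.80))
  expect_equal(nrow(res$retained), 1L)
  # second self-genome hit at 0.905: removed ("either genome")
  res <- filter_orthologous_exons(one_exon(), cross_hits(0.95),
                                  self_hits_ok(0.905))
  expect_equal(attr(res$report, "reasons"), "second_hit")
  # second cross-genome hit at 0.9099: removed
  res <- filter_orthologous_exons(one_exon(), cross_hits(0.95, 0.9099),
                                  self_hits_ok())
  expect_equal(attr(res$report, "reasons"), "second_hit")
  # exactly 0.90 is not "> 90%": kept
  res <- filter_orthologous_exons(one_exon(), cross_hits(0.95, 0.90),
                                  self_hits_ok(0.90))
  expect_equal(nrow(res$retained), 1L)
})

test_that("reciprocal criterion needs the best self-hit on the annotated locus", {
  off_locus <- rank_hits(hit_row("e1", "chrA1", 7000, 7100, 1.0))
  res <- filter_orthologous_exons(one_exon(), cross_hits(0.95), off_locus)
  expect_equal(attr(res$report, "reasons"), "no_reciprocal")
  # tie at maximal identity: passes if any tied hit overlaps the locus
  tied <- rank_hits(rbind(hit_row("e1", "chrA1", 10, 110, 1.0),
                          hit_row("e1", "chrA1", 1000, 1100, 1.0)))
  res <- filter_orthologous_exons(one_exon(), cross_hits(0.95), tied)
  expect_equal(attr(res$report, "reasons"), "second_hit")  # exact duplicate
  # missing self-hit list is an input-contract error
  expect_error(
    filter_orthologous_exons(one_exon(), cross_hits(0.95),
                             rank_hits(hit_row("zz", "chrA1", 0, 100, 1.0))),
    "self-genome")
})

test_that("retained exons carry the best cross-hit coordinates", {
  res <- filter_orthologous_exons(one_exon(), cross_hits(0.97, 0.5),
                                  self_hits_ok())
  expect_equal(res$retained$b_chrom, "chrB1")
  expect_equal(res$retained$b_start, 2000L)
  expect_equal(res$retained$b_end, 2100L)
  expect_equal(res$retained$b_identity, 0.97)
})

test_that("overlapping and bookended intervals collapse; disjoint stay apart", {
  ex <- data.frame(exon_id = c("a", "b", "c", "d"), gene_id = "g1",
                   chrom = "chr1", start = c(100L, 150L, 300L, 400L),
                   end = c(200L, 250L, 400L, 500L), strand = "+",
                   stringsAsFactors = FALSE)
  mx <- collapse_metaexons(ex)
  expect_equal(nrow(mx), 2L)
  expect_equal(mx$start, c(100L, 300L))
  expect_equal(mx$end, c(250L, 500L))        # bookended 300/400 merged
  expect_equal(mx$n_constituents, c(2L, 2L))
  expect_equal(mx$metaexon_id, c("g1.m1", "g1.m2"))
})

test_that("collapse matches the brute-force merge oracle on random instances", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(1:20, 1)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(1:80, n, replace = TRUE)
    ex <- data.frame(exon_id = paste0("e", seq_len(n)), gene_id = "g",
                     chrom = "c", start = s, end = e, strand = "+",
                     stringsAsFactors = FALSE)
    mx <- collapse_metaexons(ex)
    oracle <- merge_oracle(s, e)
    expect_equal(mx$start, oracle$start)
    expect_equal(mx$end, oracle$end)
  }
  expect_equal(nrow(collapse_metaexons(empty <- data.frame(
    exon_id = character(0), gene_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0)))), 0L)
})

# a two-gene annotation pair for gene-level filter tests; gene g1 has three
# exons with introns of 500 bp (A) whose B introns can be perturbed
gene_level_fixture <- function(b_intron1 = 500L, b_intron2 = 500L,
                               extra_a = NULL) {
  starts_a <- c(0L, 600L, 1200L)
  ends_a <- starts_a + 100L
  starts_b <- c(0L, 100L + b_intron1, 200L + b_intron1 + b_intron2)
  ends_b <- starts_b + 100L
  mx <- data.frame(
    metaexon_id = paste0("g1.m", 1:3), gene_id = "g1", chrom = "chrA1",
    start = starts_a, end = ends_a, strand = "+",
    n_constituents = 1L, constituent_exons = paste0("g1.e", 1:3),
    b_chrom = "chrB1", b_start = starts_b, b_end = ends_b, b_strand = "+",
    stringsAsFactors = FALSE)
  ann_a <- exon_records(paste0("g1.e", 1:3), "g1", "chrA1", starts_a, ends_a,
                        "+", "A")
  if (!is.null(extra_a))
    ann_a <- rbind(ann_a, extra_a)
  ann_b <- exon_records(paste0("g1.be", 1:3), "g1", "chrB1", starts_b, ends_b,
                        "+", "B")
  list(mx = mx, ann_a = ann_a, ann_b = ann_b)
}

test_that("intron-size filter boundary is inclusive at the threshold", {
  # diff 9,999: kept
  f <- gene_level_fixture(b_intron1 = 500L + 9999L)
  res <- apply_gene_level_filters(f$mx, f$ann_a, f$ann_b)
  expect_equal(nrow(res$metaexons), 3L)
  # diff 10,000: downstream metaexons removed
  f <- gene_level_fixture(b_intron1 = 500L + 10000L)
  res <- apply_gene_level_filters(f$mx, f$ann_a, f$ann_b)
  expect_equal(res$metaexons$metaexon_id, "g1.m1")
  expect_equal(sort(attr(res$report, "reasons")), rep("intron_diff", 2))
})

test_that("intron filter re-evaluates against the last kept metaexon", {
  # only the middle exon is displaced in B: removing it leaves m1-m3
  # adjacent with a consistent span, so m3 survives
  f <- gene_level_fixture(b_intron1 = 500L + 20000L,
                          b_intron2 = 500L - 20000L + 40000L)
  f$mx$b_start[3] <- f$mx$b_start[1] + 1300L   # m3 back in register with m1
  f$mx$b_end[3] <- f$mx$b_start[3] + 100L
  res <- apply_gene_level_filters(f$mx, f$ann_a, f$ann_b)
  expect_equal(res$metaexons$metaexon_id, c("g1.m1", "g1.m3"))
})

test_that("single-exon genes pass the intron filter vacuously", {
  f <- gene_level_fixture()
  one <- f$mx[1, , drop = FALSE]
  res <- apply_gene_level_filters(one, f$ann_a, f$ann_b)
  expect_equal(nrow(res$metaexons), 1L)
})

test_that("metaexons overlapping a second gene's exons are removed", {
  extra <- exon_records("g2.e1", "g2", "chrA1", 50L, 150L, "+", "A")
  f <- gene_level_fixture(extra_a = extra)
  res <- apply_gene_level_filters(f$mx, f$ann_a, f$ann_b)
  expect_false("g1.m1" %in% res$metaexons$metaexon_id)
  expect_true(all(c("g1.m2", "g1.m3") %in% res$metaexons$metaexon_id))
  expect_equal(attr(res$report, "reasons")[1], "multi_gene")
})

test_that("genes annotated on two chromosomes in either species are dropped", {
  f <- gene_level_fixture()
  f$ann_b <- rbind(f$ann_b,
                   exon_records("g1.bx", "g1", "chrB7", 0L, 100L, "+", "B"))
  res <- apply_gene_level_filters(f$mx, f$ann_a, f$ann_b)
  expect_equal(nrow(res$metaexons), 0L)
  expect_true(all(attr(res$report, "reasons") == "multi_chrom"))
})

test_that("genes absent from the target annotation get the unannotated code", {
  f <- gene_level_fixture()
  f$ann_b <- exon_records("gX.e1", "gX", "chrB1", 0L, 100L, "+", "B")
  res <- apply_gene_level_filters(f$mx, f$ann_a, f$ann_b)
  expect_equal(nrow(res$metaexons), 0L)
  expect_true(all(attr(res$report, "reasons") == "unannotated"))
})

test_that("filter reports conserve counts at every stage", {
  sim <- generate_genomes(genome_sim_config(n_genes = 12L, seed = 5,
                                            n_decoy_duplicates = 3L,
                                            n_intron_shift_genes = 2L))
  res <- build_metaexon_table(sim)
  er <- res$exon_report
  expect_equal(attr(er, "input_n"), nrow(sim$exons_a))
  expect_equal(attr(er, "retained_n") + sum(er$n_removed), attr(er, "input_n"))
  gr <- res$gene_report
  expect_equal(attr(gr, "retained_n") + sum(gr$n_removed), attr(gr, "input_n"))
  expect_equal(nrow(res$metaexons), attr(gr, "retained_n"))
})

test_that("metaexon tables round-trip through write/read", {
  f <- gene_level_fixture()
  d <- withr::local_tempdir()
  write_metaexon_table(f$mx, d)
  back <- read_metaexon_table(d)
  expect_equal(back, f$mx)
  expect_true(file.exists(file.path(d, "speciesA.metaexons.bed")))
  expect_true(file.exists(file.path(d, "speciesB.metaexons.bed")))
  # empty table: header-only TSV, empty BEDs
  d2 <- withr::local_tempdir()
  empty <- f$mx[0, , drop = FALSE]
  write_metaexon_table(empty, d2)
  back2 <- read_metaexon_table(d2)
  expect_equal(nrow(back2), 0L)
  expect_equal(names(back2), names(empty))
})
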