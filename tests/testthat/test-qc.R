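# build one cell with a prescribed total count and detected-gene number
cell_counts <- function(total, detected, n_genes = 5000L) {
  x <- integer(n_genes)
  base <- total %/% detected
  x[seq_len(detected)] <- base
  x[1] <- x[1] + total - base * detected
  x
}

test_that("cell QC boundaries match the stated inclusive/exclusive rules", {
  cases <- rbind(
    c(total = 12499, detected = 4500, kept = 0),   # "fewer than 12,500" removed
    c(total = 12500, detected = 4500, kept = 1),
    c(total = 60000, detected = 4500, kept = 1),   # 60,000 itself kept
    c(total = 60001, detected = 4500, kept = 0),   # "more than 60,000" removed
    c(total = 30000, detected = 4499, kept = 0),   # "<4500 genes" removed
    c(total = 30000, detected = 4500, kept = 1))
  m <- t(apply(cases, 1, function(r) cell_counts(r["total"], r["detected"])))
  dimnames(m) <- list(paste0("c", seq_len(nrow(m))),
                      paste0("g", seq_len(ncol(m))))
  cm <- count_matrix(m)
  res <- filter_cells(cm, qc_config())
  expect_equal(rownames(res$matrix$counts),
               rownames(m)[cases[, "kept"] == 1])
  expect_equal(unname(attr(res$report, "reasons")),
               c("low_counts", NA, NA, "high_counts", "low_genes", NA))
})

test_that("disabling the lower counts bound reproduces the two-rule variant", {
  m <- rbind(c1 = cell_counts(8000, 4600), c2 = cell_counts(70000, 4600),
             c3 = cell_counts(30000, 4000))
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  cm <- count_matrix(m)
  variant <- qc_config(min_total_counts = NA)
  res <- filter_cells(cm, variant)
  expect_equal(rownames(res$matrix$counts), "c1")  # low-count cell survives
  full <- filter_cells(cm, qc_config())
  expect_equal(nrow(full$matrix$counts), 0L)
})

test_that("log2_cpm follows its closed form", {
  m <- rbind(cellA = c(1L, 0L, 999999L),
             cellB = c(250L, 250L, 500L))
  colnames(m) <- c("g1", "g2", "g3")
  lc <- log2_cpm(m)
  expect_equal(lc["cellA", "g2"], 0)                       # zero count
  expect_equal(lc["cellA", "g1"], 1)                       # 1 of 1e6 -> log2(2)
  # uniform cell of g genes: all values log2(1 + 1e6/g) after totals cancel
  u <- matrix(7L, 2, 4, dimnames = list(c("u1", "u2"), paste0("g", 1:4)))
  expect_true(all(log2_cpm(u) == log2(1 + 1e6 / 4)))
  expect_error(log2_cpm(rbind(z = c(0L, 0L))), "zero total")
})

test_that("phenotype gene filter: strict cutoff, inclusive 10% fraction", {
  # 10 cells in group p1, 10 in p2
  labels <- rep(c("p1", "p2"), each = 10)
  m <- matrix(0, 20, 3, dimnames = list(paste0("c", 1:20), c("gA", "gB", "gC")))
  m[1, "gA"] <- 5          # >cutoff in exactly 10% of p1: retained
  m[, "gB"] <- 1           # exactly at the cutoff everywhere: removed
  m[c(1, 11), "gC"] <- 0.5 # below cutoff: removed
  kept <- filter_genes_by_phenotype(m, labels, cutoff = 1,
                                    min_cell_fraction = 0.10)
  expect_equal(kept, "gA")
  # 9% of every group is not enough: 1 of 12 cells
  labels2 <- rep("p1", 12)
  m2 <- matrix(0, 12, 1, dimnames = list(paste0("c", 1:12), "gA"))
  m2[1, 1] <- 5
  expect_equal(length(filter_genes_by_phenotype(m2, labels2, cutoff = 1)), 0L)
})

test_that("min-count gene filter matches a brute-force per-group oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n_cells <- sample(6:20, 1); n_genes <- sample(5:30, 1)
    m <- matrix(rpois(n_cells * n_genes, 0.7), n_cells, n_genes,
                dimnames = list(paste0("c", seq_len(n_cells)),
                                paste0("g", seq_len(n_genes))))
    labels <- sample(c("x", "y"), n_cells, replace = TRUE)
    kept <- filter_genes_min_count(m, labels, min_count = 1,
                                   min_cell_fraction = 0.10)
    oracle <- colnames(m)[vapply(seq_len(n_genes), function(j) {
      any(vapply(unique(labels), function(g)
        mean(m[labels == g, j] >= 1) >= 0.10, logical(1)))
    }, logical(1))]
    expect_equal(kept, oracle)
  }
  # boundary: 1 count in exactly 10% of a group is kept; all-zero removed
  m <- matrix(0L, 10, 2, dimnames = list(paste0("c", 1:10), c("g1", "g2")))
  m[1, 1] <- 1L
  expect_equal(filter_genes_min_count(m, rep("grp", 10)), "g1")
})

test_that("common_genes is a deterministic sorted intersection", {
  expect_equal(common_genes(c("b", "a"), c("c", "d")), character(0))
  expect_equal(common_genes(c("b", "a", "c"), c("c", "b", "a")),
               c("a", "b", "c"))
  map <- data.frame(gene_a = c("hA", "hB", "hC"),
                    gene_b = c("mA", "mB", "mC"), stringsAsFactors = FALSE)
  expect_equal(common_genes(c("hA", "hB"), c("mB", "mZ"), map), "hB")
})

test_that("relaxing any QC threshold never shrinks the retained sets", {
  set.seed(32)
  for (rep in 1:10) {
    cm <- random_count_matrix(15, 40, lambda = 3, seed = rep)
    base <- qc_config(min_total_counts = 100, max_total_counts = 140,
                      min_genes_detected = 30)
    n0 <- nrow(filter_cells(cm, base)$matrix$counts)
    relaxed <- list(
      qc_config(min_total_counts = 90, max_total_counts = 140,
                min_genes_detected = 30),
      qc_config(min_total_counts = 100, max_total_counts = 160,
                min_genes_detected = 30),
      qc_config(min_total_counts = 100, max_total_counts = 140,
                min_genes_detected = 25))
    for (cfg in relaxed)
      expect_gte(nrow(filter_cells(cm, cfg)$matrix$counts), n0)
    lc <- log2_cpm(matrix(rpois(300, 4) + 1, 15, 20,
                          dimnames = list(paste0("c", 1:15), paste0("g", 1:20))))
    lab <- rep(c("a", "b"), length.out = 15)
    n_strict <- length(filter_genes_by_phenotype(lc, lab, cutoff = 6))
    n_loose <- length(filter_genes_by_phenotype(lc, lab, cutoff = 5))
    expect_gte(n_loose, n_strict)
  }
})
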