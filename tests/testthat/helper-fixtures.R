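# shared fixture builders and independent oracles

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force interval merge: pairwise merge-until-fixpoint, independent of
# IRanges. Intervals are 0-based half-open; bookended intervals merge.
merge_oracle <- function(starts, ends) {
  iv <- data.frame(start = starts, end = ends)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(iv)) {
      j <- i + 1L
      while (j <= nrow(iv)) {
        if (iv$start[j] <= iv$end[i] && iv$start[i] <= iv$end[j]) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  iv[order(iv$start), , drop = FALSE]
}

# brute-force Hamming identity of two equal-length sequences
hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca == cb) / length(ca)
}

# minimal hit-table row for filter tests
hit_row <- function(id, chrom, start, end, identity, strand = "+",
                    species = "X") {
  data.frame(query_exon_id = id, target_species = species,
             target_chrom = chrom, target_start = start, target_end = end,
             strand = strand, identity = identity,
             aln_length = end - start, stringsAsFactors = FALSE)
}

# small expression config for fast tests
small_expr_config <- function(...) {
  expression_sim_config(cells_per_stage = 15L, n_genes = 600L, ...)
}

# random count matrix with labels, for QC property tests
random_count_matrix <- function(n_cells, n_genes, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_cells * n_genes, lambda), n_cells, n_genes,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("g%03d", seq_len(n_genes))))
  count_matrix(m, data.frame(
    cell_id = rownames(m),
    phenotype = sample(c("p1", "p2"), n_cells, replace = TRUE),
    stringsAsFactors = FALSE))
}

# shallow config modification preserving class
within_list <- function(cfg, ...) {
  mods <- list(...)
  for (n in names(mods)) cfg[[n]] <- mods[[n]]
  cfg
}
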