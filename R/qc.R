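#' QC configuration
#'
#' Thresholds for cell- and gene-level filtering. Defaults follow the
#' standard settings for these protocols: cells must have 12,500-60,000
#' total counts and at least 4,500 detected genes; genes must exceed a
#' log2(CPM+1) cutoff of 1 (non-UMI / non-human-primate data) or 5 (UMI /
#' human data) in at least 10% of the cells of some phenotype group.
#'
#' @param min_total_counts lower bound on per-cell total counts
#'   (inclusive); set `NA` to disable, reproducing the
#'   "<4,500 genes or >60,000 counts" filter variant.
#' @param max_total_counts upper bound on per-cell total counts (inclusive).
#' @param min_genes_detected minimum genes with count > 0 (inclusive).
#' @param gene_cutoff_log2cpm expression cutoff (strict `>`) for
#'   [filter_genes_by_phenotype()]: 1 for non-human-primate, 5 for human.
#' @param min_cell_fraction fraction of a phenotype group's cells that must
#'   pass the gene cutoff (inclusive, default 0.10).
#' @param min_count_gene_filter raw-count threshold for
#'   [filter_genes_min_count()] (default 1).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_total_counts = 12500L, max_total_counts = 60000L,
                      min_genes_detected = 4500L, gene_cutoff_log2cpm = 1,
                      min_cell_fraction = 0.10, min_count_gene_filter = 1L) {
  stopifnot(min_cell_fraction > 0, min_cell_fraction <= 1)
  if (!is.na(min_total_counts))
    stopifnot(min_total_counts < max_total_counts)
  structure(list(min_total_counts = min_total_counts,
                 max_total_counts = max_total_counts,
                 min_genes_detected = min_genes_detected,
                 gene_cutoff_log2cpm = gene_cutoff_log2cpm,
                 min_cell_fraction = min_cell_fraction,
                 min_count_gene_filter = min_count_gene_filter),
            class = "qc_config")
}

#' Cell-level QC filter
#'
#' Retains a cell iff its total counts lie within
#' `[min_total_counts, max_total_counts]` (both boundaries kept) and it
#' detects at least `min_genes_detected` genes (count > 0). With
#' `min_total_counts = NA` only the upper-counts and gene-detection rules
#' apply.
#'
#' @param matrix a [count_matrix].
#' @param config a [qc_config].
#' @return `list(matrix = retained count_matrix, report = filter_report)`;
#'   reason codes `low_counts`, `high_counts`, `low_genes` (first failing
#'   rule, in that order).
#' @export
filter_cells <- function(matrix, config = qc_config()) {
  counts <- matrix$counts
  if (nrow(counts) == 0L) {
    warning("empty count matrix")
    return(list(matrix = matrix,
                report = filter_report("cell_qc", 0L, character(0))))
  }
  totals <- rowSums(counts)
  detected <- rowSums(counts > 0)
  reason <- rep(NA_character_, nrow(counts))
  if (!is.na(config$min_total_counts))
    reason[totals < config$min_total_counts] <- "low_counts"
  reason[is.na(reason) & totals > config$max_total_counts] <- "high_counts"
  reason[is.na(reason) & detected < config$min_genes_detected] <- "low_genes"
  list(matrix = subset_cells(matrix, cells = is.na(reason)),
       report = filter_report("cell_qc", nrow(counts), reason))
}

#' log2(CPM + 1) normalization
#'
#' Library-size normalization on the full (pre-gene-filter) matrix:
#' `log2(1 + 1e6 * count / cell_total)`.
#'
#' @param matrix a [count_matrix], or a cells-x-features numeric matrix.
#' @return A numeric matrix of the same shape and dimnames.
#' @export
log2_cpm <- function(matrix) {
  counts <- if (inherits(matrix, "count_matrix")) matrix$counts else as.matrix(matrix)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts: remove them with filter_cells() first")
  log2(1 + 1e6 * counts / totals)
}

#' Gene filter on normalized expression, per phenotype group
#'
#' A gene is retained iff, in at least one phenotype group, the fraction of
#' that group's cells expressing it strictly above `cutoff` is at least
#' `min_cell_fraction`. Empty groups are ignored.
#'
#' @param log_matrix cells x genes matrix of log2(CPM+1) values.
#' @param phenotype_labels one label per cell (row).
#' @param cutoff log2(CPM+1) expression cutoff, strict (1 non-human
#'   primate, 5 human).
#' @param min_cell_fraction inclusive group-fraction threshold
#'   (default 0.10).
#' @return Character vector of retained gene ids (column order preserved).
#' @export
filter_genes_by_phenotype <- function(log_matrix, phenotype_labels,
                                      cutoff = 1, min_cell_fraction = 0.10) {
  gene_group_filter(log_matrix, phenotype_labels,
                    threshold = cutoff, strict = TRUE,
                    min_cell_fraction = min_cell_fraction)
}

#' Gene filter on raw counts, per condition group
#'
#' The raw-count analogue used for the single-species path: a gene is
#' retained iff it reaches `min_count` counts (inclusive) in at least
#' `min_cell_fraction` of the cells of some condition group.
#'
#' @param matrix a [count_matrix] or cells x genes count matrix.
#' @param group_labels one condition label per cell.
#' @param min_count inclusive count threshold (default 1).
#' @param min_cell_fraction inclusive group-fraction threshold
#'   (default 0.10).
#' @return Character vector of retained gene ids.
#' @export
filter_genes_min_count <- function(matrix, group_labels, min_count = 1L,
                                   min_cell_fraction = 0.10) {
  counts <- if (inherits(matrix, "count_matrix")) matrix$counts else as.matrix(matrix)
  gene_group_filter(counts, group_labels, threshold = min_count,
                    strict = FALSE, min_cell_fraction = min_cell_fraction)
}

gene_group_filter <- function(m, labels, threshold, strict, min_cell_fraction) {
  stopifnot(length(labels) == nrow(m))
  keep <- rep(FALSE, ncol(m))
  for (idx in split(seq_len(nrow(m)), as.character(labels))) {
    if (length(idx) == 0L) next
    pass <- if (strict) m[idx, , drop = FALSE] > threshold
            else m[idx, , drop = FALSE] >= threshold
    keep <- keep | (colMeans(pass) >= min_cell_fraction)
  }
  colnames(m)[keep]
}

#' Common gene set of two filtered datasets
#'
#' Deterministic sorted intersection of the two species' retained gene
#' sets, optionally translated through an ortholog map first.
#'
#' @param set_a,set_b character vectors of retained gene ids.
#' @param ortholog_map optional two-column `data.frame`
#'   (`gene_a`, `gene_b`) translating species-B ids into the shared
#'   namespace; omit when both sets already share one namespace (the
#'   metaexon table's).
#' @return Sorted character vector.
#' @export
common_genes <- function(set_a, set_b, ortholog_map = NULL) {
  if (!is.null(ortholog_map)) {
    stopifnot(all(c("gene_a", "gene_b") %in% names(ortholog_map)))
    set_b <- ortholog_map$gene_a[match(set_b, ortholog_map$gene_b)]
    set_b <- set_b[!is.na(set_b)]
  }
  sort(intersect(unique(set_a), unique(set_b)))
}
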