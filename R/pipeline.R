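#' Cross-species staging pipeline
#'
#' One call from two count matrices to stage assignments: optional
#' cell-level QC, log2(CPM+1) normalization, per-species phenotype-wise
#' gene filtering, common-gene intersection, per-cell rank/z-score
#' harmonization, joint PCA, and assignment of the query species' cells to
#' the reference species' stages in the selected PC subspace.
#'
#' @param matrix_a,matrix_b [count_matrix] objects; `cell_meta` must carry
#'   a `phenotype` column (stage labels for the reference species, any
#'   grouping for the query).
#' @param reference `"A"` or `"B"`: which dataset carries the embryo stage
#'   labels.
#' @param qc_a,qc_b optional [qc_config] per dataset; `NULL` skips
#'   cell-level QC (e.g. when cells are already curated).
#' @param cutoff_a,cutoff_b log2(CPM+1) gene cutoffs per dataset (1 for
#'   non-UMI / non-human-primate data, 5 for human UMI data).
#' @param min_cell_fraction group-fraction threshold for the gene filters.
#' @param k number of principal components.
#' @param pcs PC subspace for staging (default `c(2, 3)`).
#' @param method,knn_k see [assign_stage()].
#' @param stage_levels optional character vector fixing the developmental
#'   stage order; defaults to order of first appearance in the reference.
#' @return A list: `assignments` (per query cell), `pca`, `merged`
#'   (harmonized matrix), `genes` (common gene list), `qc_reports`.
#' @export
stage_cross_species <- function(matrix_a, matrix_b, reference = c("B", "A"),
                                qc_a = NULL, qc_b = NULL,
                                cutoff_a = 1, cutoff_b = 1,
                                min_cell_fraction = 0.10,
                                k = 10L, pcs = c(2L, 3L),
                                method = c("centroid", "knn"), knn_k = 15L,
                                stage_levels = NULL) {
  reference <- match.arg(reference)
  method <- match.arg(method)
  reports <- list()
  if (!is.null(qc_a)) {
    f <- filter_cells(matrix_a, qc_a)
    matrix_a <- f$matrix; reports$cells_a <- f$report
  }
  if (!is.null(qc_b)) {
    f <- filter_cells(matrix_b, qc_b)
    matrix_b <- f$matrix; reports$cells_b <- f$report
  }
  log_a <- log2_cpm(matrix_a)
  log_b <- log2_cpm(matrix_b)
  set_a <- filter_genes_by_phenotype(log_a, matrix_a$cell_meta$phenotype,
                                     cutoff = cutoff_a,
                                     min_cell_fraction = min_cell_fraction)
  set_b <- filter_genes_by_phenotype(log_b, matrix_b$cell_meta$phenotype,
                                     cutoff = cutoff_b,
                                     min_cell_fraction = min_cell_fraction)
  genes <- common_genes(set_a, set_b)
  if (length(genes) < 2L) stop("fewer than 2 common genes after filtering")
  merged <- merge_species(
    harmonize_dataset(log_a, genes, matrix_a$cell_meta, dataset = "A"),
    harmonize_dataset(log_b, genes, matrix_b$cell_meta, dataset = "B"))
  pca <- run_pca(merged, k = min(k, length(genes), nrow(merged$values)))
  is_ref <- merged$cell_meta$dataset == reference
  labels <- ifelse(is_ref, as.character(merged$cell_meta$phenotype),
                   NA_character_)
  if (is.null(stage_levels))
    stage_levels <- unique(labels[is_ref])
  labels <- factor(labels, levels = stage_levels)
  assignments <- assign_stage(pca, labels, query_mask = !is_ref,
                              pcs = pcs, method = method, knn_k = knn_k)
  list(assignments = assignments, pca = pca, merged = merged,
       genes = genes, qc_reports = reports)
}
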