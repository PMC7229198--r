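#' Per-cell rank transform
#'
#' Within each cell (row), genes are ranked ascending by abundance (lowest
#' value gets rank 1); tied values all receive the minimum rank of their
#' tie group. Ranks depend only on the within-cell ordering, which is what
#' makes the transform immune to any strictly monotone per-cell distortion
#' (platform or species effect).
#'
#' @param log_matrix cells x genes numeric matrix, normally restricted to
#'   the common gene list first.
#' @return An integer matrix of ranks, same shape and dimnames.
#' @export
rank_cells <- function(log_matrix) {
  m <- as.matrix(log_matrix)
  out <- t(apply(m, 1L, rank, ties.method = "min"))
  # apply() drops dims for single-column input
  if (ncol(m) == 1L) out <- matrix(out, ncol = 1L)
  dimnames(out) <- dimnames(m)
  storage.mode(out) <- "integer"
  out
}

#' Per-cell z-scoring of ranks
#'
#' Subtracts each cell's mean rank and divides by its sample standard
#' deviation (n-1), so every non-degenerate cell row has mean 0 and unit
#' sd. Constant cells (sd 0) are emitted as all-zero rows and flagged.
#'
#' @param rank_matrix cells x genes matrix (normally from [rank_cells()]).
#' @param cell_meta optional cell metadata carried through.
#' @param dataset provenance label (dataset id / species) stored per cell.
#' @return A `harmonized_matrix`: list with `values` (z-scored matrix),
#'   `cell_meta` (including a `dataset` column), and `degenerate` (logical
#'   flag per cell).
#' @export
zscore_cells <- function(rank_matrix, cell_meta = NULL, dataset = "dataset") {
  m <- as.matrix(rank_matrix)
  if (ncol(m) < 2L) stop("need at least 2 genes to z-score")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  degenerate <- sd == 0
  if (any(degenerate))
    warning(sum(degenerate), " constant cell(s) emitted as all-zero rows")
  z <- (m - mu) / ifelse(degenerate, 1, sd)
  z[degenerate, ] <- 0
  if (is.null(cell_meta))
    cell_meta <- data.frame(cell_id = rownames(m) %||% paste0("cell", seq_len(nrow(m))),
                            stringsAsFactors = FALSE)
  cell_meta$dataset <- dataset
  structure(list(values = z, cell_meta = cell_meta, degenerate = degenerate),
            class = "harmonized_matrix")
}

#' @export
print.harmonized_matrix <- function(x, ...) {
  cat("harmonized_matrix: ", nrow(x$values), " cells x ", ncol(x$values),
      " genes; datasets: ", paste(unique(x$cell_meta$dataset), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Harmonize one dataset (rank then z-score on the common genes)
#'
#' @param log_matrix cells x genes log2(CPM+1) matrix.
#' @param genes common gene list; columns are subset and ordered to it.
#' @param cell_meta,dataset passed to [zscore_cells()].
#' @return A `harmonized_matrix`.
#' @export
harmonize_dataset <- function(log_matrix, genes, cell_meta = NULL,
                              dataset = "dataset") {
  missing_genes <- setdiff(genes, colnames(log_matrix))
  if (length(missing_genes))
    stop("genes absent from matrix: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  zscore_cells(rank_cells(log_matrix[, genes, drop = FALSE]),
               cell_meta = cell_meta, dataset = dataset)
}

#' Merge two harmonized datasets on a shared gene list
#'
#' Row-concatenation (dataset A first, then B, original cell order), with
#' per-cell metadata and dataset provenance carried through. The gene
#' lists must be identical and identically ordered.
#'
#' @param harmonized_a,harmonized_b `harmonized_matrix` objects.
#' @param common_genes optional gene list to check both against.
#' @return A merged `harmonized_matrix`.
#' @export
merge_species <- function(harmonized_a, harmonized_b, common_genes = NULL) {
  ga <- colnames(harmonized_a$values)
  gb <- colnames(harmonized_b$values)
  if (!identical(ga, gb))
    stop("gene lists differ between the two datasets")
  if (!is.null(common_genes) && !identical(ga, as.character(common_genes)))
    stop("gene lists do not match the supplied common gene list")
  meta_cols <- union(names(harmonized_a$cell_meta), names(harmonized_b$cell_meta))
  pad <- function(meta) {
    for (col in setdiff(meta_cols, names(meta))) meta[[col]] <- NA
    meta[, meta_cols, drop = FALSE]
  }
  structure(list(
    values = rbind(harmonized_a$values, harmonized_b$values),
    cell_meta = rbind(pad(harmonized_a$cell_meta), pad(harmonized_b$cell_meta)),
    degenerate = c(harmonized_a$degenerate, harmonized_b$degenerate)),
    class = "harmonized_matrix")
}
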