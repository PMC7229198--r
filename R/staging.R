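#' Principal component analysis of a harmonized (or normalized) matrix
#'
#' Deterministic full-SVD PCA via [stats::prcomp] with column centering and
#' no per-gene variance scaling (rows are already rank-z-scored on the
#' harmonized path). Component signs are fixed so that each component's
#' largest-magnitude gene loading is positive, making results reproducible
#' across BLAS implementations up to that convention.
#'
#' @param matrix a `harmonized_matrix` or a cells x genes numeric matrix.
#' @param k number of components to keep (`k >= 1`,
#'   `k <= min(cells, genes)`).
#' @param center center columns before the SVD (default `TRUE`).
#' @param scale. scale columns to unit variance (default `FALSE`).
#' @return A `pca_result`: list with `scores` (cells x k), `loadings`
#'   (genes x k), `variance_fraction` (per kept component, relative to the
#'   total variance), `k`, and `cell_meta` when available.
#' @export
run_pca <- function(matrix, k = 10L, center = TRUE, scale. = FALSE) {
  meta <- NULL
  if (inherits(matrix, "harmonized_matrix")) {
    meta <- matrix$cell_meta
    matrix <- matrix$values
  }
  m <- as.matrix(matrix)
  if (!all(is.finite(m))) stop("matrix contains non-finite values")
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  if (k > min(dim(m))) stop("k exceeds min(cells, genes)")
  p <- stats::prcomp(m, center = center, scale. = scale., rank. = k)
  # sign convention: largest-|loading| gene positive per component
  for (j in seq_len(k)) {
    lead <- which.max(abs(p$rotation[, j]))
    if (p$rotation[lead, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  total_var <- sum(p$sdev^2)
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 variance_fraction = (p$sdev^2 / total_var)[seq_len(k)],
                 k = k, cell_meta = meta),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: ", nrow(x$scores), " cells, k = ", x$k,
      "; variance fractions: ",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)), collapse = " "),
      if (x$k > 5) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' PCA of a single dataset on normalized expression
#'
#' The within-species view: PCA on log2(CPM+1) values without the
#' cross-species rank harmonization, e.g. to display a subpopulation
#' continuum inside one species.
#'
#' @param log_matrix cells x genes log2(CPM+1) matrix.
#' @inheritParams run_pca
#' @return A `pca_result`.
#' @export
pca_single_dataset <- function(log_matrix, k = 10L, center = TRUE,
                               scale. = FALSE) {
  run_pca(log_matrix, k = k, center = center, scale. = scale.)
}

#' Assign query cells to reference stages in a PC subspace
#'
#' Quantifies the placement of query cells on the reference developmental
#' axis. In the subspace spanned by the selected components (by default PCs
#' 2 and 3, the axes that resolve pre/post-implantation identity and
#' post-implantation progression once PC1 has absorbed the species/platform
#' offset), each query cell is assigned either to the stage with the
#' nearest reference centroid (`method = "centroid"`) or to the majority
#' stage among its `knn_k` nearest reference cells (`method = "knn"`).
#' Ties are broken by smaller mean distance to the tied stages' reference
#' cells, then by earliest developmental stage, and flagged.
#'
#' @param pca a `pca_result` covering reference and query cells.
#' @param reference_labels stage label per cell; `NA` for non-reference
#'   cells. A factor's level order defines the developmental stage order;
#'   otherwise order of first appearance is used.
#' @param query_mask logical per cell, `TRUE` for cells to assign
#'   (default: every unlabeled cell).
#' @param pcs component indices spanning the staging subspace
#'   (default `c(2, 3)`).
#' @param method `"centroid"` or `"knn"`.
#' @param knn_k neighbors for the knn method (default 15).
#' @return `data.frame` with `cell_id`, `assigned_stage`, `tie` (logical),
#'   and one `dist_<stage>` column per stage (Euclidean distance to the
#'   stage centroid, or mean distance to the stage's cells among the knn
#'   vote's candidates); attribute `pcs_used` records the subspace.
#' @export
assign_stage <- function(pca, reference_labels, query_mask = NULL,
                         pcs = c(2L, 3L), method = c("centroid", "knn"),
                         knn_k = 15L) {
  method <- match.arg(method)
  scores <- pca$scores
  n <- nrow(scores)
  stopifnot(length(reference_labels) == n)
  if (any(pcs > ncol(scores)))
    stop("requested PCs not present in the pca_result")
  if (is.null(query_mask)) query_mask <- is.na(reference_labels)
  stages <- if (is.factor(reference_labels)) levels(reference_labels) else
    unique(as.character(reference_labels[!is.na(reference_labels)]))
  labels <- as.character(reference_labels)
  counts <- table(factor(labels, levels = stages))
  if (any(counts == 0L)) {
    warning("stages with 0 reference cells excluded: ",
            paste(stages[counts == 0L], collapse = ", "))
    stages <- stages[counts > 0L]
  }
  if (!length(stages)) stop("no labeled reference cells")
  sub <- scores[, pcs, drop = FALSE]
  ref_idx <- which(!is.na(labels) & labels %in% stages)
  q_idx <- which(query_mask)
  centroids <- do.call(rbind, lapply(stages, function(s)
    colMeans(sub[ref_idx[labels[ref_idx] == s], , drop = FALSE])))
  rownames(centroids) <- stages

  ids <- rownames(scores) %||% paste0("cell", seq_len(n))
  out <- data.frame(cell_id = ids[q_idx],
                    assigned_stage = NA_character_, tie = FALSE,
                    stringsAsFactors = FALSE)
  dist_mat <- matrix(NA_real_, length(q_idx), length(stages),
                     dimnames = list(NULL, paste0("dist_", stages)))

  for (i in seq_along(q_idx)) {
    x <- sub[q_idx[i], ]
    cd <- sqrt(colSums((t(centroids) - x)^2))
    if (method == "centroid") {
      dist_mat[i, ] <- cd
      best <- which(cd == min(cd))
      out$tie[i] <- length(best) > 1L
      out$assigned_stage[i] <- stages[best[1L]]  # stage order = precedence
    } else {
      rd <- sqrt(rowSums((sub[ref_idx, , drop = FALSE] -
                            matrix(x, length(ref_idx), length(pcs),
                                   byrow = TRUE))^2))
      nn <- order(rd)[seq_len(min(knn_k, length(rd)))]
      votes <- table(factor(labels[ref_idx][nn], levels = stages))
      mean_d <- vapply(stages, function(s) {
        sel <- labels[ref_idx][nn] == s
        if (any(sel)) mean(rd[nn][sel]) else Inf
      }, numeric(1))
      dist_mat[i, ] <- mean_d
      top <- which(votes == max(votes))
      if (length(top) > 1L) {
        out$tie[i] <- TRUE
        top <- top[order(mean_d[top], top)]  # mean distance, then stage order
      }
      out$assigned_stage[i] <- stages[top[1L]]
    }
  }
  out <- cbind(out, as.data.frame(dist_mat))
  attr(out, "pcs_used") <- pcs
  attr(out, "stage_order") <- stages
  out
}
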