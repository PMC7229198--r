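#' Cells-by-features count matrix with cell metadata
#'
#' The container that flows through counting, QC, normalization and
#' harmonization: an integer matrix with cells as rows and features
#' (metaexons or genes) as columns, plus a cell metadata table (species,
#' phenotype / stage label, individual or embryo id).
#'
#' @param counts integer matrix, cells x features, nonnegative; rownames
#'   are cell ids, colnames feature ids (supplied dimnames win over
#'   `cell_meta$cell_id` ordering checks).
#' @param cell_meta `data.frame` with a `cell_id` column covering every row
#'   of `counts`, in the same order; other columns are free-form metadata.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `cell_meta`.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(dimnames(counts)) && length(counts) == 0L)
    dimnames(counts) <- list(character(0), character(0))
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0L) stop("counts must have cell ids as rownames")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0L) stop("counts must have feature ids as colnames")
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("cell and feature ids must be unique")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(cell_meta))
    cell_meta <- data.frame(cell_id = rownames(counts), stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_meta))
    stop("cell_meta must contain a cell_id column")
  if (nrow(cell_meta) != nrow(counts) ||
      (nrow(counts) > 0L &&
         !identical(as.character(cell_meta$cell_id), rownames(counts))))
    stop("cell_meta must cover every cell, in matrix row order")
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " features; meta columns: ",
      paste(setdiff(names(x$cell_meta), "cell_id"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells and/or features
#'
#' @param x a [count_matrix].
#' @param cells,features index vectors (logical, integer or id character).
#' @return A [count_matrix].
#' @export
subset_cells <- function(x, cells = NULL, features = NULL) {
  counts <- x$counts
  meta <- x$cell_meta
  if (!is.null(cells)) {
    counts <- counts[cells, , drop = FALSE]
    meta <- meta[match(rownames(counts), meta$cell_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(features))
    counts <- counts[, features, drop = FALSE]
  count_matrix(counts, meta)
}

#' Write / read a count matrix
#'
#' `format = "MTX"` writes a MatrixMarket `matrix.mtx` (cells x features)
#' with companion `cells.tsv` (cell metadata) and `features.tsv` id files;
#' `format = "TSV"` writes a dense `counts.tsv` plus `cells.tsv`. Both
#' round-trip losslessly through [read_matrix()].
#'
#' @param matrix a [count_matrix].
#' @param dir output directory (created if missing).
#' @param format `"MTX"` or `"TSV"`.
#' @return `write_matrix()` invisibly returns `dir`; `read_matrix()`
#'   returns a [count_matrix].
#' @export
write_matrix <- function(matrix, dir, format = c("MTX", "TSV")) {
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  utils::write.table(matrix$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (format == "MTX") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(matrix$counts, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(colnames(matrix$counts), file.path(dir, "features.tsv"))
  } else {
    df <- data.frame(cell_id = rownames(matrix$counts), matrix$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_matrix
#' @param path directory written by [write_matrix()].
#' @export
read_matrix <- function(path, format = c("MTX", "TSV")) {
  format <- match.arg(format)
  meta <- utils::read.delim(file.path(path, "cells.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  if (format == "MTX") {
    m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    feats <- readLines(file.path(path, "features.tsv"))
    if (nrow(m) != nrow(meta) || ncol(m) != length(feats))
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match id files (", nrow(meta), " cells, ",
           length(feats), " features)")
    storage.mode(m) <- "integer"
    dimnames(m) <- list(meta$cell_id, feats)
  } else {
    df <- utils::read.delim(file.path(path, "counts.tsv"),
                            stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- as.character(df[[1]])
    if (!identical(rownames(m), as.character(meta$cell_id)))
      stop("counts.tsv cell ids do not match cells.tsv")
  }
  count_matrix(m, meta)
}
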