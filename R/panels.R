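#' Derive stage-specific gene panels from a labeled reference
#'
#' A transparent effect-size + detection rule: a gene enters the panel for
#' stage set S iff its mean log-expression in S-cells exceeds the mean in
#' all other cells by at least `min_effect` log2 units AND it is detected
#' (value > 0) in at least `min_detect_frac` of the S-cells. Panels are
#' derived for each requested stage set (e.g. ICM only; ICM plus
#' pre-implantation epiblast; all epiblast; late post-implantation plus
#' gastrulation), mirroring how stage-marker rows are organized in
#' embryo-reference summaries. Panels may instead be supplied directly via
#' [read_panels()] to bypass derivation.
#'
#' @param reference log-expression matrix (cells x genes) of the labeled
#'   reference.
#' @param stage_labels stage label per reference cell.
#' @param stage_sets named list; each element is the character vector of
#'   stage labels the panel marks. Default: one panel per individual stage.
#' @param min_effect minimum mean log2 difference (S vs complement),
#'   default 1.
#' @param min_detect_frac minimum detected fraction within S, default 0.5.
#' @return A list of `gene_panel` objects (`panel_id`, `stage_set`,
#'   `genes`, `derivation_params`); panels with no qualifying genes are
#'   dropped. Stages with fewer than 2 cells are excluded with a warning.
#' @export
derive_stage_panels <- function(reference, stage_labels, stage_sets = NULL,
                                min_effect = 1, min_detect_frac = 0.5) {
  m <- as.matrix(reference)
  stopifnot(length(stage_labels) == nrow(m))
  labels <- as.character(stage_labels)
  tab <- table(labels)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("stages with < 2 cells excluded: ", paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    m <- m[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L)
    stop("need at least 2 stages with >= 2 cells")
  if (is.null(stage_sets)) {
    stage_sets <- as.list(unique(labels))
    names(stage_sets) <- unique(labels)
  }
  params <- list(min_effect = min_effect, min_detect_frac = min_detect_frac)
  panels <- list()
  for (pid in names(stage_sets)) {
    s <- stage_sets[[pid]]
    in_s <- labels %in% s
    if (!any(in_s) || all(in_s)) next
    eff <- colMeans(m[in_s, , drop = FALSE]) - colMeans(m[!in_s, , drop = FALSE])
    det <- colMeans(m[in_s, , drop = FALSE] > 0)
    genes <- colnames(m)[eff >= min_effect & det >= min_detect_frac]
    if (!length(genes)) next
    panels[[pid]] <- structure(list(panel_id = pid, stage_set = s,
                                    genes = genes,
                                    derivation_params = params),
                               class = "gene_panel")
  }
  panels
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("gene_panel '", x$panel_id, "' (stages: ",
      paste(x$stage_set, collapse = "+"), "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' Panel score distributions per cell group
#'
#' Per cell, the panel score is the mean expression over the panel's genes;
#' scores are then summarized per cell group (the data behind per-panel
#' violin rows: median, quartiles, extremes, plus the underlying values).
#'
#' @param matrix cells x genes expression matrix.
#' @param panels list of `gene_panel` objects (or a `data.frame` with
#'   `panel_id`, `gene_id`).
#' @param group_labels group label per cell; empty groups are skipped with
#'   a warning.
#' @return `list(summary = , scores = )`: `summary` has one row per
#'   (panel, group) with `n`, `min`, `q1`, `median`, `q3`, `max`; `scores`
#'   holds the per-cell values (`panel_id`, `cell_id`, `group`, `score`).
#' @export
panel_distributions <- function(matrix, panels, group_labels) {
  m <- as.matrix(matrix)
  stopifnot(length(group_labels) == nrow(m))
  if (is.data.frame(panels))
    panels <- panel_list_from_table(panels)
  groups <- unique(as.character(group_labels))
  summary_rows <- list()
  score_rows <- list()
  ids <- rownames(m) %||% paste0("cell", seq_len(nrow(m)))
  for (p in panels) {
    missing <- setdiff(p$genes, colnames(m))
    if (length(missing))
      stop("panel '", p$panel_id, "' genes absent from matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    score <- rowMeans(m[, p$genes, drop = FALSE])
    for (g in groups) {
      sel <- group_labels == g
      if (!any(sel)) {
        warning("empty group '", g, "' skipped")
        next
      }
      v <- score[sel]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        panel_id = p$panel_id, group = g, n = length(v),
        min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
        stringsAsFactors = FALSE)
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        panel_id = p$panel_id, cell_id = ids[sel], group = g, score = v,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summary_rows),
       scores = do.call(rbind, score_rows))
}

#' Write / read gene panels as two-column TSV
#'
#' @param panels list of `gene_panel` objects.
#' @param path TSV path (`panel_id`, `gene_id`).
#' @return `read_panels()` returns a list of `gene_panel` objects (stage
#'   sets are not stored in the file and are set to the panel id).
#' @export
write_panels <- function(panels, path) {
  df <- do.call(rbind, lapply(panels, function(p)
    data.frame(panel_id = p$panel_id, gene_id = p$genes,
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(panel_id = character(0), gene_id = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  panel_list_from_table(df)
}

panel_list_from_table <- function(df) {
  stopifnot(all(c("panel_id", "gene_id") %in% names(df)))
  sp <- split(df$gene_id, df$panel_id)
  mapply(function(pid, genes)
    structure(list(panel_id = pid, stage_set = character(0), genes = genes,
                   derivation_params = list()),
              class = "gene_panel"),
    names(sp), sp, SIMPLIFY = FALSE)
}
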