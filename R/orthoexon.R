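#' @title Orthologous-exon filter chain
#' @description
#' Exon-level orthology filtering between a source species (A, whose
#' annotation defines the exon universe) and a target species (B). An exon
#' survives iff its best hit in genome B reaches the identity floor, its
#' best self-genome hit maps back to its own annotated locus, and it has no
#' near-identical second match in either genome. Survivors carry the B
#' coordinates of their best cross-species hit.
#'
#' @param exons an [exon_records] table (species A annotation).
#' @param hits_cross ranked hits of the A exons against genome B
#'   (see [compute_exon_hits()] / [read_psl()]).
#' @param hits_self ranked hits of the A exons against genome A. Required:
#'   the reciprocal ("maps back") criterion and the genome-A half of the
#'   second-hit rule are evaluated on this list.
#' @param min_identity identity floor for the best cross-species hit
#'   (inclusive; default 0.92).
#' @param second_hit_identity exclusion threshold for a rank-2 hit in either
#'   genome (strict; default 0.90).
#' @param min_mapback_overlap minimum overlap in bp between the best
#'   self-hit and the annotated interval for the reciprocal criterion.
#'
#' @details
#' The second match in genome A is the rank-2 self-hit (rank 1 being the
#' annotated locus); the second match in genome B is the rank-2 cross-hit.
#' When several self-hits tie at the maximal identity (exact duplicate
#' loci), the reciprocal criterion passes if any of them overlaps the
#' annotated interval on the annotated strand, so exact duplications are
#' attributed to the second-hit rule rather than to failed mapping.
#'
#' Reason codes, applied in order: `low_identity` (no cross-hit or best
#' cross identity below the floor), `no_reciprocal` (best self-hit off the
#' annotated locus), `second_hit` (rank-2 match above the exclusion
#' threshold in either genome).
#'
#' @return `list(retained = , report = )`: the retained exon table gains
#'   columns `b_chrom`, `b_start`, `b_end`, `b_strand`, `b_identity`;
#'   `report` is a [filter_report] with one row per reason code.
#' @export
filter_orthologous_exons <- function(exons, hits_cross, hits_self,
                                     min_identity = 0.92,
                                     second_hit_identity = 0.90,
                                     min_mapback_overlap = 1L) {
  stopifnot(nrow(exons) >= 1L)
  if (missing(hits_self) || is.null(hits_self))
    stop("hits_self is required: the reciprocal and second-hit criteria need self-genome hits")
  cross <- split(hits_cross, hits_cross$query_exon_id)
  self  <- split(hits_self, hits_self$query_exon_id)

  reason <- rep(NA_character_, nrow(exons))
  bc <- data.frame(b_chrom = NA_character_, b_start = NA_integer_,
                   b_end = NA_integer_, b_strand = NA_character_,
                   b_identity = NA_real_, stringsAsFactors = FALSE)[rep(1L, nrow(exons)), ]

  for (i in seq_len(nrow(exons))) {
    id <- exons$exon_id[i]
    hc <- cross[[id]]
    hs <- self[[id]]
    # 1. identity floor on the best cross-species hit ("at least" -> inclusive)
    if (is.null(hc) || nrow(hc) == 0L || max(hc$identity) < min_identity) {
      reason[i] <- "low_identity"
      next
    }
    # 2. reciprocal: a maximal-identity self-hit overlaps the annotated locus
    if (is.null(hs) || nrow(hs) == 0L)
      stop("exon ", id, " has no self-genome hit list (input contract)")
    best_self <- hs[hs$identity == max(hs$identity), , drop = FALSE]
    ov <- best_self$strand == exons$strand[i] &
      best_self$target_chrom == exons$chrom[i] &
      (pmin(best_self$target_end, exons$end[i]) -
         pmax(best_self$target_start, exons$start[i])) >= min_mapback_overlap
    if (!any(ov)) {
      reason[i] <- "no_reciprocal"
      next
    }
    # 3. second match > threshold in either genome (strict ">")
    second <- c(hs$identity[hs$rank == 2L], hc$identity[hc$rank == 2L])
    if (length(second) && any(second > second_hit_identity)) {
      reason[i] <- "second_hit"
      next
    }
    top <- hc[hc$rank == 1L, , drop = FALSE][1L, ]
    bc$b_chrom[i] <- top$target_chrom
    bc$b_start[i] <- top$target_start
    bc$b_end[i] <- top$target_end
    bc$b_strand[i] <- top$strand
    bc$b_identity[i] <- top$identity
  }

  retained <- cbind(as.data.frame(exons)[is.na(reason), , drop = FALSE],
                    bc[is.na(reason), , drop = FALSE])
  rownames(retained) <- NULL
  list(retained = retained,
       report = filter_report("exon_orthology", nrow(exons), reason))
}

#' Collapse retained exons into metaexons
#'
#' Within each gene, overlapping or bookended exon intervals (isoform
#' variants of the same genomic exon) are merged into a single metaexon;
#' disjoint intervals yield distinct metaexons. When the exon table carries
#' cross-species coordinates (`b_*` columns from
#' [filter_orthologous_exons()]), each metaexon is paired with the span of
#' its constituents' coordinates in the other genome.
#'
#' @param retained_exons exon table with `exon_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open), optionally `b_*` columns.
#' @return A metaexon `data.frame` ordered by (chrom, start), with
#'   `metaexon_id` (`<gene>.m<n>`), per-species coordinates,
#'   `n_constituents` and a comma-separated `constituent_exons` column.
#'   If constituents of one metaexon map to different target chromosomes,
#'   `b_chrom` is set `NA` (flagged for the gene-level chromosome filter).
#' @export
collapse_metaexons <- function(retained_exons) {
  has_b <- "b_chrom" %in% names(retained_exons)
  if (nrow(retained_exons) == 0L) return(empty_metaexons(has_b))
  pieces <- list()
  for (key in split(seq_len(nrow(retained_exons)),
                    paste(retained_exons$gene_id, retained_exons$chrom, sep = "\r"))) {
    ex <- retained_exons[key, , drop = FALSE]
    ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)  # 1-based closed
    red <- IRanges::reduce(ir)                                   # merges bookended
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red, maxgap = 0L))
    for (j in seq_along(red)) {
      members <- ex[grp == j, , drop = FALSE]
      row <- data.frame(
        gene_id = members$gene_id[1L], chrom = members$chrom[1L],
        start = IRanges::start(red)[j] - 1L, end = IRanges::end(red)[j],
        strand = members$strand[1L],
        n_constituents = nrow(members),
        constituent_exons = paste(sort(members$exon_id), collapse = ","),
        stringsAsFactors = FALSE)
      if (has_b) {
        bchrom <- unique(members$b_chrom)
        row$b_chrom <- if (length(bchrom) == 1L) bchrom else NA_character_
        row$b_start <- min(members$b_start)
        row$b_end <- max(members$b_end)
        row$b_strand <- members$b_strand[1L]
      }
      pieces[[length(pieces) + 1L]] <- row
    }
  }
  mx <- do.call(rbind, pieces)
  mx <- mx[order(mx$chrom, mx$start, mx$gene_id), , drop = FALSE]
  mx$metaexon_id <- paste0(mx$gene_id, ".m",
                           stats::ave(seq_len(nrow(mx)), mx$gene_id, FUN = seq_along))
  rownames(mx) <- NULL
  mx[, c("metaexon_id", setdiff(names(mx), "metaexon_id"))]
}

empty_metaexons <- function(has_b = TRUE) {
  df <- data.frame(metaexon_id = character(0), gene_id = character(0),
                   chrom = character(0), start = integer(0), end = integer(0),
                   strand = character(0), n_constituents = integer(0),
                   constituent_exons = character(0), stringsAsFactors = FALSE)
  if (has_b) {
    df$b_chrom <- character(0); df$b_start <- integer(0)
    df$b_end <- integer(0); df$b_strand <- character(0)
  }
  df
}

#' Gene-level metaexon filters
#'
#' Removes metaexons that fail gene-level consistency checks:
#' \itemize{
#'   \item `unannotated`: the gene is absent from the target-species
#'     annotation;
#'   \item `multi_gene`: the metaexon interval overlaps annotated exons of
#'     more than one gene (checked in both species);
#'   \item `multi_chrom`: the gene is annotated on two or more chromosomes
#'     in either species (or constituents map to inconsistent target
#'     chromosomes);
#'   \item `intron_diff`: the intron to the adjacent retained metaexon of
#'     the same gene differs in length between the species by at least
#'     `max_intron_diff` bp (inclusive boundary), suggestive of assembly or
#'     annotation error. Evaluated in a single 5'->3' pass: when a pair
#'     fails, the downstream member is removed and the kept member is
#'     compared with the next.
#' }
#'
#' @param metaexons output of [collapse_metaexons()], with `b_*` columns.
#' @param annotations_a,annotations_b [exon_records] for species A and B
#'   (shared gene namespace).
#' @param max_intron_diff removal threshold in bp, inclusive
#'   (default 10000).
#' @return `list(metaexons = , report = )`.
#' @export
apply_gene_level_filters <- function(metaexons, annotations_a, annotations_b,
                                     max_intron_diff = 10000L) {
  n0 <- nrow(metaexons)
  if (n0 == 0L)
    return(list(metaexons = metaexons,
                report = filter_report("gene_level", 0L, character(0))))
  reason <- rep(NA_character_, n0)

  map_a <- gene_chrom_map(annotations_a)
  map_b <- gene_chrom_map(annotations_b)

  # unannotated in the target species
  reason[!(metaexons$gene_id %in% map_b$gene_id)] <- "unannotated"

  # overlap with annotated exons of a second gene, in either species
  multi_a <- overlaps_other_gene(metaexons$chrom, metaexons$start,
                                 metaexons$end, metaexons$gene_id, annotations_a)
  multi_b <- overlaps_other_gene(metaexons$b_chrom, metaexons$b_start,
                                 metaexons$b_end, metaexons$gene_id, annotations_b)
  reason[is.na(reason) & (multi_a | multi_b)] <- "multi_gene"

  # gene on >= 2 chromosomes in either species, or inconsistent B mapping
  nchrom_a <- table(unique(map_a)$gene_id)
  nchrom_b <- table(unique(map_b)$gene_id)
  bad_genes <- union(names(nchrom_a)[nchrom_a >= 2L], names(nchrom_b)[nchrom_b >= 2L])
  reason[is.na(reason) &
           (metaexons$gene_id %in% bad_genes | is.na(metaexons$b_chrom))] <- "multi_chrom"

  # adjacent intron-size consistency, per gene, 5'->3'
  for (idx in split(seq_len(n0), metaexons$gene_id)) {
    idx <- idx[is.na(reason[idx])]
    idx <- idx[order(metaexons$start[idx])]
    if (length(idx) < 2L) next
    kept <- idx[1L]
    for (i in idx[-1L]) {
      if (!identical(metaexons$b_chrom[i], metaexons$b_chrom[kept])) {
        reason[i] <- "multi_chrom"
        next
      }
      intron_a <- max(0L, metaexons$start[i] - metaexons$end[kept])
      intron_b <- interval_gap(metaexons$b_start[kept], metaexons$b_end[kept],
                               metaexons$b_start[i], metaexons$b_end[i])
      if (abs(intron_a - intron_b) >= max_intron_diff) {
        reason[i] <- "intron_diff"
      } else {
        kept <- i
      }
    }
  }

  out <- metaexons[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  list(metaexons = out, report = filter_report("gene_level", n0, reason))
}

overlaps_other_gene <- function(chrom, start, end, gene, annotations) {
  res <- logical(length(chrom))
  ok <- !is.na(chrom)
  if (!any(ok)) return(res)
  q <- GenomicRanges::GRanges(chrom[ok], IRanges::IRanges(start[ok] + 1L, end[ok]))
  s <- GenomicRanges::GRanges(annotations$chrom,
                              IRanges::IRanges(annotations$start + 1L, annotations$end))
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  other <- gene[ok][S4Vectors::queryHits(hits)] !=
    annotations$gene_id[S4Vectors::subjectHits(hits)]
  res[ok][unique(S4Vectors::queryHits(hits)[other])] <- TRUE
  res
}

# unsigned gap between two 0-based half-open intervals (0 if they overlap)
interval_gap <- function(s1, e1, s2, e2) {
  if (s2 >= e1) s2 - e1 else if (s1 >= e2) s1 - e2 else 0L
}

#' Filter audit report
#'
#' Tabulates removals by reason code for one filtering stage and records
#' the conservation identity `input = retained + removed`.
#'
#' @param stage label of the filtering stage.
#' @param input_n number of records entering the stage.
#' @param reasons character vector with one element per input record:
#'   `NA` for retained records, a reason code otherwise. May also be a
#'   zero-length vector with `input_n = 0`.
#' @return A `data.frame` of class `filter_report` with columns `stage`,
#'   `reason`, `n_removed`, and attributes `input_n`, `retained_n`.
#' @export
filter_report <- function(stage, input_n, reasons) {
  stopifnot(length(reasons) == input_n)
  tab <- table(reasons[!is.na(reasons)])
  df <- data.frame(stage = rep(stage, length(tab)),
                   reason = if (length(tab)) names(tab) else character(0),
                   n_removed = as.integer(tab), stringsAsFactors = FALSE)
  attr(df, "input_n") <- as.integer(input_n)
  attr(df, "retained_n") <- as.integer(input_n - sum(df$n_removed))
  attr(df, "reasons") <- reasons
  class(df) <- c("filter_report", "data.frame")
  df
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter stage '", x$stage[1] %||% "?", "': ",
      attr(x, "input_n"), " in, ", attr(x, "retained_n"), " retained\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
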