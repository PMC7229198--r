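#' Feature intervals of a metaexon table, per species
#'
#' Flattens a metaexon table into the feature layout [assign_reads()]
#' expects, using either the source-species (A) or target-species (B)
#' coordinates.
#'
#' @param metaexons a metaexon table (see [collapse_metaexons()]).
#' @param species `"A"` or `"B"`.
#' @return `data.frame` with `feature_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @export
metaexon_features <- function(metaexons, species = c("A", "B")) {
  species <- match.arg(species)
  if (species == "A") {
    data.frame(feature_id = metaexons$metaexon_id, gene_id = metaexons$gene_id,
               chrom = metaexons$chrom, start = metaexons$start,
               end = metaexons$end, strand = metaexons$strand,
               stringsAsFactors = FALSE)
  } else {
    ok <- !is.na(metaexons$b_chrom)
    data.frame(feature_id = metaexons$metaexon_id[ok],
               gene_id = metaexons$gene_id[ok],
               chrom = metaexons$b_chrom[ok], start = metaexons$b_start[ok],
               end = metaexons$b_end[ok], strand = metaexons$b_strand[ok],
               stringsAsFactors = FALSE)
  }
}

#' Assign aligned-read intervals to metaexons or genes
#'
#' featureCounts-style unique assignment: a read is counted once for the
#' feature it overlaps by at least `min_overlap` bp. Reads overlapping
#' features of two or more genes are discarded as ambiguous; reads
#' overlapping several metaexons of one gene are attributed to the feature
#' with the largest overlap (leftmost on ties). Gene-level counts are the
#' sum of the gene's metaexon-level counts by construction.
#'
#' @param reads `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`, `-` or `.`), `cell_id`; see [read_bed_reads()].
#' @param features feature intervals (see [metaexon_features()]).
#' @param level `"metaexon"` or `"gene"`.
#' @param stranded if `TRUE`, only same-strand overlaps count
#'   (default `FALSE`: protocols differ in strandedness).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return A [count_matrix] (all features as columns, cells sorted by id)
#'   with an `assign_log` attribute:
#'   `c(assigned, ambiguous, unassigned)`, which sums to `nrow(reads)`.
#' @export
assign_reads <- function(reads, features, level = c("metaexon", "gene"),
                         stranded = FALSE, min_overlap = 1L) {
  level <- match.arg(level)
  stopifnot(all(reads$start < reads$end), all(features$start < features$end))
  cells <- sort(unique(as.character(reads$cell_id)))
  feat_ids <- if (level == "metaexon") features$feature_id else
    sort(unique(features$gene_id))
  counts <- matrix(0L, nrow = length(cells), ncol = length(feat_ids),
                   dimnames = list(cells, feat_ids))
  n_assigned <- n_ambig <- n_unassigned <- 0L

  if (nrow(reads)) {
    q <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$start + 1L, reads$end),
                                strand = ifelse(reads$strand %in% c("+", "-"),
                                                reads$strand, "*"))
    s <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start + 1L, features$end),
                                strand = features$strand)
    ov <- GenomicRanges::findOverlaps(q, s, minoverlap = min_overlap,
                                      ignore.strand = !stranded)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    width <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(q)[qh], GenomicRanges::ranges(s)[sh]))

    hit_split <- split(seq_along(qh), qh)
    for (key in names(hit_split)) {
      ri <- as.integer(key)
      j <- hit_split[[key]]
      genes <- unique(features$gene_id[sh[j]])
      if (length(genes) >= 2L) {
        n_ambig <- n_ambig + 1L
        next
      }
      # within the gene: largest overlap, leftmost feature on ties
      best <- j[order(-width[j], features$start[sh[j]])][1L]
      fid <- if (level == "metaexon") features$feature_id[sh[best]] else genes
      ci <- as.character(reads$cell_id[ri])
      counts[ci, fid] <- counts[ci, fid] + 1L
      n_assigned <- n_assigned + 1L
    }
    n_unassigned <- nrow(reads) - n_assigned - n_ambig
  }

  out <- count_matrix(counts)
  attr(out, "assign_log") <- c(assigned = n_assigned, ambiguous = n_ambig,
                               unassigned = n_unassigned)
  out
}

#' Read BED intervals as reads
#'
#' BED6 (or BED4+) input: the `name` column is taken as the cell or sample
#' id. Coordinates stay 0-based half-open.
#'
#' @param path BED file.
#' @return `data.frame` suitable for [assign_reads()].
#' @export
read_bed_reads <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             cell_id = if (!is.null(gr$name)) as.character(gr$name)
                       else paste0("read", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Sum counts within individuals (or any cell grouping)
#'
#' Collapses the matrix to one row per group by summing counts; total
#' counts are conserved. Metadata columns constant within a group are
#' carried through, varying ones dropped.
#'
#' @param matrix a [count_matrix].
#' @param group_key name of the `cell_meta` column to group by
#'   (default `"individual"`); grouping by `cell_id` is the identity.
#' @return A [count_matrix] with one row per group.
#' @export
sum_within_individuals <- function(matrix, group_key = "individual") {
  meta <- matrix$cell_meta
  if (!group_key %in% names(meta))
    stop("cell_meta has no column '", group_key, "'")
  g <- as.character(meta[[group_key]])
  if (anyNA(g)) stop("missing values in grouping column '", group_key, "'")
  summed <- rowsum(matrix$counts, group = g, reorder = TRUE)
  storage.mode(summed) <- "integer"
  groups <- rownames(summed)
  keep <- vapply(meta, function(col)
    all(vapply(split(as.character(col), g), function(v)
      length(unique(v)) == 1L, logical(1))), logical(1))
  new_meta <- data.frame(cell_id = groups, stringsAsFactors = FALSE)
  for (col in setdiff(names(meta)[keep], "cell_id"))
    new_meta[[col]] <- vapply(split(as.character(meta[[col]]), g), `[`,
                              character(1), 1L)[groups]
  count_matrix(summed, new_meta)
}
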