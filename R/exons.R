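#' Exon record table
#'
#' Builds the table of annotated exons on which the orthology filters act.
#' Coordinates are stored 0-based half-open; GTF/GFF input (1-based closed)
#' is converted on read.
#'
#' @param exon_id character vector of unique exon identifiers.
#' @param gene_id character vector, one gene per exon.
#' @param chrom chromosome names.
#' @param start,end integer 0-based half-open coordinates, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param species species label carried through the pipeline.
#'
#' @return A `data.frame` with class `exon_records`, one row per exon.
#' @export
exon_records <- function(exon_id, gene_id, chrom, start, end, strand, species) {
  df <- data.frame(
    exon_id = as.character(exon_id),
    gene_id = as.character(gene_id),
    chrom   = as.character(chrom),
    start   = as.integer(start),
    end     = as.integer(end),
    strand  = as.character(strand),
    species = as.character(species),
    stringsAsFactors = FALSE
  )
  validate_exon_records(df)
  class(df) <- c("exon_records", "data.frame")
  df
}

validate_exon_records <- function(df) {
  stopifnot(all(df$start < df$end))
  if (anyDuplicated(df$exon_id))
    stop("exon_id values must be unique within a species")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(df)
}

#' Read exon records from a GTF/GFF file
#'
#' Keeps `exon` features only and converts coordinates to the internal
#' 0-based half-open convention. Exons lacking an `exon_id` attribute get a
#' deterministic `<gene_id>.e<n>` identifier.
#'
#' @param path GTF/GFF3 file.
#' @param species species label to stamp on the records.
#' @return An [exon_records] table.
#' @export
read_exon_gtf <- function(path, species) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    stop("no exon features in ", path)
  ids <- if (!is.null(gr$exon_id)) as.character(gr$exon_id) else rep(NA_character_, length(gr))
  gene <- as.character(gr$gene_id)
  if (anyNA(ids)) {
    miss <- is.na(ids)
    ids[miss] <- paste0(gene[miss], ".e",
                        stats::ave(seq_along(gene), gene, FUN = seq_along)[miss])
  }
  exon_records(
    exon_id = ids, gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    species = species
  )
}

#' Gene-to-chromosome map from exon records
#'
#' @param exons an [exon_records] table.
#' @return `data.frame` with columns `gene_id`, `chrom`, one row per
#'   observed (gene, chromosome) pair.
#' @export
gene_chrom_map <- function(exons) {
  unique(data.frame(gene_id = exons$gene_id, chrom = exons$chrom,
                    stringsAsFactors = FALSE))
}

#' Extract exon sequences from a genome
#'
#' Minus-strand exons are reverse-complemented so every returned sequence
#' reads 5'->3' in the transcript orientation.
#'
#' @param exons an [exon_records] table.
#' @param genome a named [Biostrings::DNAStringSet] (or FASTA path).
#' @return A [Biostrings::DNAStringSet] named by `exon_id`.
#' @export
exon_sequences <- function(exons, genome) {
  genome <- as_genome(genome)
  missing_chrom <- setdiff(unique(exons$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosomes absent from genome: ", paste(missing_chrom, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(exons)), function(i) {
    s <- Biostrings::subseq(genome[[exons$chrom[i]]],
                            start = exons$start[i] + 1L, end = exons$end[i])
    if (exons$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  names(seqs) <- exons$exon_id
  seqs
}

as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (is.character(x))
    x <- Biostrings::DNAStringSet(x)
  if (!methods::is(x, "DNAStringSet"))
    stop("genome must be a DNAStringSet, named character vector, or FASTA path")
  if (length(x) && (is.null(names(x)) || anyDuplicated(names(x))))
    stop("genome sequences must have unique names")
  # keep only the first whitespace-delimited token of FASTA headers
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
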