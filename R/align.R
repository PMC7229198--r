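#' Align exon sequences to a genome (k-mer seed, ungapped extension)
#'
#' A small-scale local aligner for desk-sized genomes: exact k-mer seeds are
#' looked up in a positional index of the target, each seed diagonal is
#' extended without gaps across the full query length (clipped at contig
#' ends), and identity is computed as matching bases over aligned columns.
#' Both query orientations are searched against the forward genome strand.
#' For genome-scale work, ingest external BLAT output with [read_psl()]
#' instead.
#'
#' @param exon_seqs named [Biostrings::DNAStringSet] (or named character
#'   vector) of query exon sequences, 5'->3'.
#' @param target_genome named [Biostrings::DNAStringSet], character vector,
#'   or FASTA path.
#' @param target_species label stored in the `target_species` column.
#' @param min_report_identity hits below this identity are not reported.
#' @param k seed length in bp; must not exceed the shortest query (shorter
#'   queries are reported with zero hits and a warning).
#'
#' @return An alignment-hit `data.frame` with columns `query_exon_id`,
#'   `target_species`, `target_chrom`, `target_start`, `target_end`
#'   (0-based half-open), `strand`, `identity`, `aln_length`, `rank`
#'   (1 = best hit of that query in this genome; ties broken by longer
#'   alignment, then leftmost coordinate).
#' @export
compute_exon_hits <- function(exon_seqs, target_genome, target_species,
                              min_report_identity = 0.5, k = 11L) {
  if (methods::is(exon_seqs, "DNAStringSet")) exon_seqs <- as.character(exon_seqs)
  if (is.null(names(exon_seqs)) || anyDuplicated(names(exon_seqs)))
    stop("exon sequences must have unique names")
  if (length(exon_seqs) == 0L) stop("no query sequences")
  genome <- as_genome(target_genome)
  if (length(genome) == 0L || all(Biostrings::width(genome) == 0L))
    stop("empty target genome")
  k <- as.integer(k)

  short <- nchar(exon_seqs) < k
  if (any(short))
    warning(sum(short), " exon(s) shorter than seed k=", k,
            " reported with zero hits")

  index <- lapply(as.character(genome), kmer_index, k = k)
  tchars <- lapply(as.character(genome), function(s) strsplit(s, "", fixed = TRUE)[[1]])

  out <- vector("list", length(exon_seqs))
  for (qi in seq_along(exon_seqs)) {
    qname <- names(exon_seqs)[qi]
    if (short[qi]) next
    hits <- list()
    for (std in c("+", "-")) {
      q <- exon_seqs[[qi]]
      if (std == "-")
        q <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
      qchars <- strsplit(q, "", fixed = TRUE)[[1]]
      qlen <- length(qchars)
      qkmers <- substring(q, 1:(qlen - k + 1L), k:qlen)
      for (chrom in names(genome)) {
        idx <- index[[chrom]]
        pos <- idx[qkmers]            # list: genome start positions per query k-mer
        qpos <- rep(seq_along(qkmers), lengths(pos))
        tpos <- unlist(pos, use.names = FALSE)
        if (!length(tpos)) next
        # query base i (1-based) sits at 0-based target position i + d
        diag <- unique(tpos - qpos)
        tc <- tchars[[chrom]]
        tlen <- length(tc)
        for (d in diag) {
          lo <- max(1L, -d); hi <- min(qlen, tlen - 1L - d)
          if (hi - lo + 1L < k) next
          qr <- lo:hi
          tr <- qr + d + 1L
          ident <- sum(qchars[qr] == tc[tr]) / length(qr)
          if (ident < min_report_identity) next
          hits[[length(hits) + 1L]] <- data.frame(
            query_exon_id = qname, target_species = target_species,
            target_chrom = chrom,
            target_start = d + lo,           # 0-based
            target_end   = d + hi + 1L,      # half-open
            strand = std, identity = ident,
            aln_length = hi - lo + 1L, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) out[[qi]] <- do.call(rbind, hits)
  }
  rank_hits(do.call(rbind, c(out, list(empty_hits(target_species)))))
}

kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  split(seq(0L, n - k), kmers)   # 0-based start positions per k-mer
}

empty_hits <- function(target_species = character(0)) {
  data.frame(query_exon_id = character(0), target_species = character(0),
             target_chrom = character(0), target_start = integer(0),
             target_end = integer(0), strand = character(0),
             identity = numeric(0), aln_length = integer(0),
             stringsAsFactors = FALSE)
}

#' Rank alignment hits per query
#'
#' Orders each query's hits by identity (descending), alignment length
#' (descending), then leftmost (chromosome, start), and assigns `rank`
#' (1 = best).
#'
#' @param hits an alignment-hit `data.frame` (see [compute_exon_hits()]).
#' @return The same table, reordered, with a `rank` column.
#' @export
rank_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    hits$rank <- integer(0)
    return(hits)
  }
  o <- order(hits$query_exon_id, -hits$identity, -hits$aln_length,
             hits$target_chrom, hits$target_start)
  hits <- hits[o, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_exon_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

#' Read a BLAT PSL hit table
#'
#' Parses PSL (with or without the 5-line header) into the package's
#' alignment-hit table. Identity is computed as
#' `matches / (matches + misMatches + qNumInsert + tNumInsert)`, so gapped
#' BLAT alignments are penalized per gap opening, matching how external
#' genome-scale hit tables are normally summarized.
#'
#' @param path PSL file.
#' @param target_species label stored in the `target_species` column.
#' @return A ranked alignment-hit `data.frame` (see [compute_exon_hits()]).
#' @export
read_psl <- function(path, target_species) {
  lines <- readLines(path)
  body <- grep("^[0-9]", lines, value = TRUE)
  if (!length(body)) return(rank_hits(empty_hits()))
  f <- utils::read.table(text = body, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(f) < 17L) stop("not a PSL table: ", path)
  denom <- f[[1]] + f[[2]] + f[[5]] + f[[7]]
  rank_hits(data.frame(
    query_exon_id = as.character(f[[10]]),
    target_species = target_species,
    target_chrom = as.character(f[[14]]),
    target_start = as.integer(f[[16]]),
    target_end = as.integer(f[[17]]),
    strand = substr(as.character(f[[9]]), 1L, 1L),
    identity = ifelse(denom > 0, f[[1]] / denom, 0),
    aln_length = as.integer(f[[13]]) - as.integer(f[[12]]),
    stringsAsFactors = FALSE))
}
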