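#' Write / read a metaexon table
#'
#' `write_metaexon_table()` emits one BED file per species (0-based
#' half-open, name = metaexon id) plus `metaexons.tsv` holding the full
#' mapping (metaexon id, gene id, coordinates in both species, constituent
#' exons). `read_metaexon_table()` restores the table losslessly from the
#' TSV.
#'
#' @param metaexons a metaexon table (see [collapse_metaexons()]).
#' @param dir output directory (created if missing).
#' @param species_a,species_b labels used in the BED file names.
#' @return `write_metaexon_table()` invisibly returns the paths written;
#'   `read_metaexon_table()` returns the metaexon `data.frame`.
#' @export
write_metaexon_table <- function(metaexons, dir,
                                 species_a = "speciesA", species_b = "speciesB") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  tsv <- file.path(dir, "metaexons.tsv")
  utils::write.table(metaexons, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  beds <- character(0)
  bed_a <- file.path(dir, paste0(species_a, ".metaexons.bed"))
  write_bed(metaexons$chrom, metaexons$start, metaexons$end,
            metaexons$metaexon_id, metaexons$strand, bed_a)
  beds <- c(beds, bed_a)
  if ("b_chrom" %in% names(metaexons)) {
    bed_b <- file.path(dir, paste0(species_b, ".metaexons.bed"))
    ok <- !is.na(metaexons$b_chrom)
    write_bed(metaexons$b_chrom[ok], metaexons$b_start[ok],
              metaexons$b_end[ok], metaexons$metaexon_id[ok],
              metaexons$b_strand[ok], bed_b)
    beds <- c(beds, bed_b)
  }
  invisible(c(tsv, beds))
}

write_bed <- function(chrom, start, end, name, strand, path) {
  if (length(chrom) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                               strand = strand)
  gr$name <- name
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_metaexon_table
#' @export
read_metaexon_table <- function(dir) {
  tsv <- if (dir.exists(dir)) file.path(dir, "metaexons.tsv") else dir
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE, colClasses = "character")
  for (col in intersect(c("start", "end", "b_start", "b_end", "n_constituents"),
                        names(df)))
    df[[col]] <- as.integer(df[[col]])
  df
}
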