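#' Configuration for the toy two-species genome simulator
#'
#' @param n_genes number of genes planted per genome.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_len,intron_len bp ranges `c(min, max)`.
#' @param ortholog_divergence per-base substitution rate applied to
#'   species-B exon copies (0 = perfect orthologs).
#' @param n_decoy_duplicates exons that additionally get an exact duplicate
#'   copy planted elsewhere (alternating between the two genomes), the
#'   scenario the second-hit filter exists for.
#' @param n_intron_shift_genes genes whose first intron is lengthened in
#'   species B by `intron_shift_bp`, the scenario the intron-size filter
#'   exists for.
#' @param intron_shift_bp size of that lengthening (default 12000, above
#'   the 10 kb removal boundary).
#' @param intergenic_len bp of random sequence between genes.
#' @param seed RNG seed; the same seed reproduces the genomes byte for
#'   byte.
#' @return A list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_genes = 50L, exons_per_gene = c(2L, 4L),
                              exon_len = c(90L, 150L),
                              intron_len = c(200L, 400L),
                              ortholog_divergence = 0.02,
                              n_decoy_duplicates = 10L,
                              n_intron_shift_genes = 5L,
                              intron_shift_bp = 12000L,
                              intergenic_len = 300L, seed = 1L) {
  stopifnot(ortholog_divergence >= 0, ortholog_divergence <= 1,
            all(exon_len > 0), all(intron_len > 0),
            n_decoy_duplicates + n_intron_shift_genes <= n_genes)
  structure(as.list(environment()), class = "genome_sim_config")
}

#' Generate two toy genomes with planted orthologs, decoys and intron
#' shifts
#'
#' Species A carries `n_genes` genes of random sequence; species B carries
#' the same genes in the same order, with every exon copied from A and
#' mutated at `ortholog_divergence`, introns and intergenic sequence drawn
#' fresh. A subset of exons gets an exact duplicate planted in one of the
#' genomes (alternating A/B); a disjoint subset of genes gets its first
#' intron lengthened in B by `intron_shift_bp`. The truth table records
#' which filter should remove which exon: decoy-bearing exons via
#' `second_hit`; for an intron-shifted gene, every exon downstream of the
#' shifted intron via `intron_diff`.
#'
#' @param config a [genome_sim_config].
#' @return A list with `genome_a`, `genome_b`
#'   ([Biostrings::DNAStringSet]), `exons_a`, `exons_b` ([exon_records]),
#'   `truth` (`data.frame`: `exon_id`, `gene_id`, `category`
#'   (`clean`/`decoy`/`intron_shift`), `expected_reason` (`NA` for
#'   retained)), and `config`.
#' @export
generate_genomes <- function(config = genome_sim_config()) {
  stopifnot(inherits(config, "genome_sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes

  n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], ng,
                 replace = TRUE)
  shift_genes <- seq_len(config$n_intron_shift_genes)            # need >= 2 exons
  n_ex[shift_genes] <- pmax(n_ex[shift_genes], 2L)
  decoy_pool <- setdiff(seq_len(ng), shift_genes)
  decoy_genes <- decoy_pool[seq_len(config$n_decoy_duplicates)]

  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  mutate_seq <- function(s, rate) {
    if (rate == 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }

  genes <- vector("list", ng)
  for (g in seq_len(ng)) {
    ne <- n_ex[g]
    exon_seqs <- vapply(seq_len(ne), function(i)
      rand_seq(sample(config$exon_len[1]:config$exon_len[2], 1L)), character(1))
    intron_len_a <- if (ne > 1L)
      sample(config$intron_len[1]:config$intron_len[2], ne - 1L, replace = TRUE)
    else integer(0)
    intron_len_b <- intron_len_a
    if (g %in% shift_genes)
      intron_len_b[1L] <- intron_len_b[1L] + config$intron_shift_bp
    genes[[g]] <- list(id = sprintf("gene%03d", g), exon_seqs = exon_seqs,
                       intron_len_a = intron_len_a, intron_len_b = intron_len_b)
  }

  build_genome <- function(which_sp) {
    chrom_name <- if (which_sp == "A") "chrA1" else "chrB1"
    parts <- character(0)
    pos <- 0L
    rows <- list()
    for (g in seq_len(ng)) {
      gn <- genes[[g]]
      spacer <- rand_seq(config$intergenic_len)
      parts <- c(parts, spacer); pos <- pos + nchar(spacer)
      ilen <- if (which_sp == "A") gn$intron_len_a else gn$intron_len_b
      for (i in seq_along(gn$exon_seqs)) {
        eseq <- if (which_sp == "A") gn$exon_seqs[i] else
          mutate_seq(gn$exon_seqs[i], config$ortholog_divergence)
        rows[[length(rows) + 1L]] <- data.frame(
          exon_id = sprintf("%s.e%d", gn$id, i), gene_id = gn$id,
          chrom = chrom_name, start = pos, end = pos + nchar(eseq),
          strand = "+", stringsAsFactors = FALSE)
        parts <- c(parts, eseq); pos <- pos + nchar(eseq)
        if (i < length(gn$exon_seqs)) {
          intron <- rand_seq(ilen[i])
          parts <- c(parts, intron); pos <- pos + nchar(intron)
        }
      }
    }
    # decoys hosted by this genome: exact copy of the host-genome exon
    exon_tab <- do.call(rbind, rows)
    seq_full <- paste(parts, collapse = "")
    for (k in seq_along(decoy_genes)) {
      host <- if (k %% 2L == 1L) "A" else "B"
      if (host != which_sp) next
      gid <- genes[[decoy_genes[k]]]$id
      target_exon <- sprintf("%s.e1", gid)
      row <- exon_tab[exon_tab$exon_id == target_exon, ]
      copy <- substr(seq_full, row$start + 1L, row$end)
      seq_full <- paste0(seq_full, rand_seq(config$intergenic_len), copy)
    }
    list(seq = seq_full, exons = exon_tab, chrom = chrom_name)
  }

  ga <- build_genome("A")
  gb <- build_genome("B")

  genome_a <- Biostrings::DNAStringSet(stats::setNames(ga$seq, ga$chrom))
  genome_b <- Biostrings::DNAStringSet(stats::setNames(gb$seq, gb$chrom))

  truth_rows <- list()
  for (g in seq_len(ng)) {
    gn <- genes[[g]]
    for (i in seq_along(gn$exon_seqs)) {
      eid <- sprintf("%s.e%d", gn$id, i)
      if (g %in% decoy_genes && i == 1L) {
        cat_ <- "decoy"; expect <- "second_hit"
      } else if (g %in% shift_genes && i >= 2L) {
        cat_ <- "intron_shift"; expect <- "intron_diff"
      } else {
        cat_ <- "clean"; expect <- NA_character_
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        exon_id = eid, gene_id = gn$id, category = cat_,
        expected_reason = expect, stringsAsFactors = FALSE)
    }
  }

  list(genome_a = genome_a, genome_b = genome_b,
       exons_a = exon_records(ga$exons$exon_id, ga$exons$gene_id,
                              ga$exons$chrom, ga$exons$start, ga$exons$end,
                              ga$exons$strand, species = "A"),
       exons_b = exon_records(gb$exons$exon_id, gb$exons$gene_id,
                              gb$exons$chrom, gb$exons$start, gb$exons$end,
                              gb$exons$strand, species = "B"),
       truth = do.call(rbind, truth_rows), config = config)
}

#' Run the full orthologous-metaexon pipeline on simulated (or real-style)
#' inputs
#'
#' Aligns every species-A exon against both genomes with the built-in
#' aligner, applies the exon-level orthology filters, collapses survivors
#' into metaexons and applies the gene-level filters.
#'
#' @param sim output of [generate_genomes()], or a list with the same
#'   elements (`genome_a`, `genome_b`, `exons_a`, `exons_b`).
#' @param min_identity,second_hit_identity,max_intron_diff filter
#'   thresholds (defaults 0.92 / 0.90 / 10000).
#' @param min_report_identity,k aligner settings (see
#'   [compute_exon_hits()]).
#' @return A list: `metaexons` (final table), `retained_exons`,
#'   `exon_report`, `gene_report`, `hits_cross`, `hits_self`.
#' @export
build_metaexon_table <- function(sim, min_identity = 0.92,
                                 second_hit_identity = 0.90,
                                 max_intron_diff = 10000L,
                                 min_report_identity = 0.5, k = 11L) {
  seqs <- exon_sequences(sim$exons_a, sim$genome_a)
  hits_self <- compute_exon_hits(seqs, sim$genome_a, target_species = "A",
                                 min_report_identity = min_report_identity, k = k)
  hits_cross <- compute_exon_hits(seqs, sim$genome_b, target_species = "B",
                                  min_report_identity = min_report_identity, k = k)
  flt <- filter_orthologous_exons(sim$exons_a, hits_cross, hits_self,
                                  min_identity = min_identity,
                                  second_hit_identity = second_hit_identity)
  mx <- collapse_metaexons(flt$retained)
  gl <- apply_gene_level_filters(mx, sim$exons_a, sim$exons_b,
                                 max_intron_diff = max_intron_diff)
  list(metaexons = gl$metaexons, retained_exons = flt$retained,
       exon_report = flt$report, gene_report = gl$report,
       hits_cross = hits_cross, hits_self = hits_self)
}
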