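#' Configuration for the stage-structured two-species count simulator
#'
#' Emulates the statistical structure the cross-species harmonization is
#' designed for: a shared developmental expression program, observed
#' through two platforms that differ by a strictly monotone distortion of
#' expression, library-size variation, protocol-specific overdispersion
#' and dropout.
#'
#' Stage-informative genes come in two classes. Trajectory genes have a
#' log2 mean linear in normalized stage time (slope sign random), giving
#' the data a one-dimensional developmental axis; stage-specific markers
#' are elevated by `stage_effect` log2 units in exactly one stage, the
#' panel-derivation target. All remaining genes are stage-flat baseline.
#'
#' @param stages ordered character vector of stage labels (developmental
#'   order).
#' @param cells_per_stage cells per stage, per species.
#' @param n_genes total genes.
#' @param stage_marker_fraction fraction of genes that are stage-specific
#'   markers (split evenly across stages).
#' @param trajectory_fraction fraction of genes with a linear trajectory
#'   profile.
#' @param stage_effect amplitude in log2 units: marker elevation within
#'   its stage, and the full dynamic range of trajectory genes.
#' @param species_gamma named vector `c(A = , B = )` of monotone
#'   distortion exponents (expression is raised elementwise to this power
#'   before normalization); `B = 1.6` emulates the compressive/expansive
#'   platform difference between protocols.
#' @param species_gene_bias_log2sd per-species sd (log2 units) of a fixed
#'   gene-wise capture bias (3'-bias, length bias and similar
#'   protocol-specific efficiencies). Constant across cells within a
#'   species, so it reorders genes between the platforms — the batch
#'   component that a within-cell rank transform cannot remove and that
#'   joint PCA is expected to isolate on its own component (default A 0,
#'   B 1.5).
#' @param library_size_meanlog,library_size_sdlog log-normal per-cell
#'   library sizes, per species (named vectors recycled from scalars).
#' @param dropout_rate per-species probability that an observed count is
#'   zeroed (UMI protocols lose slightly more molecules; default A 0.15,
#'   B 0.10).
#' @param dispersion per-species negative-binomial dispersion (1/size);
#'   0 means Poisson noise (non-UMI amplification noise is larger;
#'   default A 0.3, B 0.6).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline of relative
#'   gene expression.
#' @param deterministic if `TRUE`, skip all sampling: counts are the
#'   rounded expected counts, dropout ignored (for exactness tests).
#' @param seed RNG seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(
    stages = c("ICM", "preEPI", "postEPI-early", "postEPI-late", "Gast"),
    cells_per_stage = 40L, n_genes = 2000L,
    stage_marker_fraction = 0.15, trajectory_fraction = 0.20,
    stage_effect = 1.5,
    species_gamma = c(A = 1, B = 1.6),
    species_gene_bias_log2sd = c(A = 0, B = 1.5),
    library_size_meanlog = c(A = log(30000), B = log(30000)),
    library_size_sdlog = c(A = 0.25, B = 0.25),
    dropout_rate = c(A = 0.15, B = 0.10),
    dispersion = c(A = 0.3, B = 0.6),
    baseline_meanlog = log(10), baseline_sdlog = 1,
    deterministic = FALSE, seed = 1L) {
  as_sp <- function(x) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, 2L), c("A", "B"))
    stopifnot(all(c("A", "B") %in% names(x)))
    x
  }
  stopifnot(cells_per_stage > 0, length(stages) >= 1,
            stage_marker_fraction >= 0, trajectory_fraction >= 0,
            stage_marker_fraction + trajectory_fraction <= 1)
  cfg <- as.list(environment())
  cfg$as_sp <- NULL
  for (f in c("species_gamma", "species_gene_bias_log2sd",
              "library_size_meanlog", "library_size_sdlog",
              "dropout_rate", "dispersion"))
    cfg[[f]] <- as_sp(cfg[[f]])
  stopifnot(all(cfg$dropout_rate >= 0), all(cfg$dropout_rate <= 1),
            all(cfg$dispersion >= 0), all(cfg$species_gamma > 0))
  structure(cfg, class = "expression_sim_config")
}

#' Simulate stage-structured count matrices for two species
#'
#' Shared gene programs: baseline log-normal means modulated by trajectory
#' slopes and stage-specific marker effects (identical in both species).
#' Per species, expected relative expression is distorted elementwise by
#' `x^gamma`, renormalized, scaled to a log-normal library size, sampled
#' with negative-binomial (or Poisson) noise and thinned by Bernoulli
#' dropout. The same seed reproduces the matrices exactly.
#'
#' @param config an [expression_sim_config].
#' @return A list: `A`, `B` ([count_matrix] each, `cell_meta` columns
#'   `species`, `phenotype` (true stage), `individual`); `truth` with
#'   `genes` (`gene_id`, `class` = baseline/trajectory/stage_marker,
#'   `marker_stage`, `slope`) and `log2_profile` (genes x stages planted
#'   log2 relative means); `config`.
#' @export
simulate_counts <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  S <- length(config$stages)
  G <- config$n_genes
  genes <- sprintf("g%04d", seq_len(G))

  n_mark <- round(config$stage_marker_fraction * G)
  n_traj <- round(config$trajectory_fraction * G)
  class_ <- rep("baseline", G)
  class_[seq_len(n_mark)] <- "stage_marker"
  class_[n_mark + seq_len(n_traj)] <- "trajectory"
  marker_stage <- rep(NA_character_, G)
  marker_stage[seq_len(n_mark)] <- rep_len(config$stages, n_mark)
  slope <- rep(0, G)
  slope[class_ == "trajectory"] <- sample(c(-1, 1), n_traj, replace = TRUE)

  baseline <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
  t_s <- if (S > 1) (seq_len(S) - 1) / (S - 1) else 0.5
  # genes x stages planted log2 relative means
  log2_profile <- matrix(log2(baseline), G, S,
                         dimnames = list(genes, config$stages))
  for (s in seq_len(S)) {
    log2_profile[, s] <- log2_profile[, s] +
      config$stage_effect * slope * (t_s[s] - 0.5)
    is_m <- !is.na(marker_stage) & marker_stage == config$stages[s]
    log2_profile[is_m, s] <- log2_profile[is_m, s] + config$stage_effect
  }

  sample_species <- function(sp) {
    n_cells <- S * config$cells_per_stage
    stage_of <- rep(config$stages, each = config$cells_per_stage)
    ids <- sprintf("%s_%s_c%03d", sp, stage_of, seq_len(n_cells))
    lib <- stats::rlnorm(n_cells, config$library_size_meanlog[[sp]],
                         if (config$deterministic) 0 else config$library_size_sdlog[[sp]])
    counts <- matrix(0L, n_cells, G, dimnames = list(ids, genes))
    gamma <- config$species_gamma[[sp]]
    bias_sd <- config$species_gene_bias_log2sd[[sp]]
    bias <- if (bias_sd > 0) 2^stats::rnorm(G, 0, bias_sd) else rep(1, G)
    for (c_i in seq_len(n_cells)) {
      mu <- 2^log2_profile[, match(stage_of[c_i], config$stages)]
      y <- (mu^gamma) * bias
      p <- y / sum(y)
      m <- lib[c_i] * p
      if (config$deterministic) {
        x <- round(m)
      } else {
        disp <- config$dispersion[[sp]]
        x <- if (disp > 0) stats::rnbinom(G, mu = m, size = 1 / disp)
             else stats::rpois(G, m)
        dr <- config$dropout_rate[[sp]]
        if (dr > 0) x[stats::runif(G) < dr] <- 0L
      }
      counts[c_i, ] <- as.integer(x)
    }
    count_matrix(counts, data.frame(
      cell_id = ids, species = sp, phenotype = stage_of,
      individual = sprintf("%s_ind%d", sp, (seq_len(n_cells) - 1L) %% 2L + 1L),
      stringsAsFactors = FALSE))
  }

  a <- sample_species("A")
  b <- sample_species("B")
  list(A = a, B = b,
       truth = list(genes = data.frame(gene_id = genes, class = class_,
                                       marker_stage = marker_stage,
                                       slope = slope, stringsAsFactors = FALSE),
                    log2_profile = log2_profile),
       config = config)
}

#' Write a deterministic suite of small fixtures
#'
#' Materializes everything the pipeline consumes as plain-text files:
#' two FASTA genomes with GTF annotations and the planted-exon truth
#' table, plus two count matrices (TSV) with cell labels and the
#' gene-truth table. Regeneration with the same seed is byte-identical.
#'
#' @param out_dir output directory (created if missing).
#' @param seed seed forwarded to both simulators.
#' @param genome_config,expression_config optional configs; their `seed`
#'   field is overridden by `seed`.
#' @return Invisibly, the paths written.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L,
                               genome_config = genome_sim_config(),
                               expression_config = expression_sim_config()) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create directory ", out_dir)
  genome_config$seed <- seed
  expression_config$seed <- seed

  sim <- generate_genomes(genome_config)
  fa_a <- file.path(out_dir, "speciesA.fa")
  fa_b <- file.path(out_dir, "speciesB.fa")
  Biostrings::writeXStringSet(sim$genome_a, fa_a)
  Biostrings::writeXStringSet(sim$genome_b, fa_b)
  gtf_a <- file.path(out_dir, "speciesA.gtf")
  gtf_b <- file.path(out_dir, "speciesB.gtf")
  write_exon_gtf(sim$exons_a, gtf_a)
  write_exon_gtf(sim$exons_b, gtf_b)
  genome_truth <- file.path(out_dir, "genome_truth.tsv")
  utils::write.table(sim$truth, genome_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cs <- simulate_counts(expression_config)
  dir_a <- file.path(out_dir, "counts_A")
  dir_b <- file.path(out_dir, "counts_B")
  write_matrix(cs$A, dir_a, format = "TSV")
  write_matrix(cs$B, dir_b, format = "TSV")
  gene_truth <- file.path(out_dir, "gene_truth.tsv")
  utils::write.table(cs$truth$genes, gene_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(c(fa_a, fa_b, gtf_a, gtf_b, genome_truth,
              file.path(dir_a, "counts.tsv"), file.path(dir_b, "counts.tsv"),
              gene_truth))
}

#' Write exon records as GTF
#'
#' @param exons an [exon_records] table.
#' @param path output GTF path.
#' @return Invisibly, `path`.
#' @export
write_exon_gtf <- function(exons, path) {
  gr <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start + 1L, exons$end),
                               strand = exons$strand)
  gr$source <- "orthostage"
  gr$type <- "exon"
  gr$gene_id <- exons$gene_id
  gr$exon_id <- exons$exon_id
  rtracklayer::export(gr, path, format = "GTF")
  invisible(path)
}
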