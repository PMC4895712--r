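#' Simulation configuration for a synthetic resequencing panel
#'
#' Bundles and validates every parameter of the synthetic-panel generator.
#' The defaults describe a small but fully featured study: a two-pseudomolecule
#' 2 Mb genome carrying 20 genes, five re-sequenced genotypes plus a reference
#' control, SNPs at one site per kb and indels at a tenth of that, a 30%
#' heterozygous fraction, 25 line-specific variants per genotype, three gene
#' deletions and three duplications per genotype, and three structural events
#' of each class (CTX, ITX, INV) per genotype.
#'
#' @param n_chromosomes Number of pseudomolecules.
#' @param chromosome_length Length of each pseudomolecule in bases.
#' @param n_genes Number of gene models packed onto the genome.
#' @param gene_length_range Length range (min, max) of a gene span in bases.
#' @param n_samples Number of re-sequenced genotypes (the reference control is
#'   generated in addition and is never counted here).
#' @param snp_rate Expected panel-level SNP sites per base (union across
#'   genotypes).
#' @param indel_rate Expected panel-level indel sites per base.
#' @param indel_length_max Maximum indel length in bases; indels are drawn
#'   uniformly on `1:indel_length_max`. The 1-58 bp range is the small-indel
#'   definition used throughout the package.
#' @param het_fraction Probability that a planted genotype call is heterozygous.
#' @param n_line_specific Line-specific variants planted per genotype (sites
#'   carried by exactly one genotype).
#' @param n_gene_deletions,n_gene_duplications Gene deletion / duplication
#'   events planted per genotype.
#' @param n_sv_per_type Structural events planted per genotype for each of
#'   CTX (inter-chromosomal translocation), ITX (intra-chromosomal
#'   translocation) and INV (inversion).
#' @param base_depth Mean sequencing depth (X).
#' @param depth_noise_sd Standard deviation of the depth noise (X).
#' @param depth_bin Width in bases of the piecewise-constant depth bins.
#' @param read_length Read length in bases used for discordant mate spans.
#' @param insert_size_mean,insert_size_sd Insert-size model of the library, in
#'   bases; governs mate-position jitter and the discordance threshold.
#' @param sv_support Discordant pairs emitted per planted structural event.
#' @param forced_effects Named integer vector: number of coding variants whose
#'   effect class is forced by construction (names are effect classes such as
#'   `"STOP_GAINED"`); these carry their class in the truth set. Use an empty
#'   vector to disable.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical outputs.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chromosome_length = 1e6,
                       n_genes = 20,
                       gene_length_range = c(1200L, 2400L),
                       n_samples = 5,
                       snp_rate = 1e-3,
                       indel_rate = 1e-4,
                       indel_length_max = 58,
                       het_fraction = 0.3,
                       n_line_specific = 25,
                       n_gene_deletions = 3,
                       n_gene_duplications = 3,
                       n_sv_per_type = 3,
                       base_depth = 10,
                       depth_noise_sd = 1,
                       depth_bin = 100,
                       read_length = 100,
                       insert_size_mean = 400,
                       insert_size_sd = 40,
                       sv_support = 6,
                       forced_effects = default_forced_effects(),
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_samples = as.integer(n_samples),
    snp_rate = snp_rate,
    indel_rate = indel_rate,
    indel_length_max = as.integer(indel_length_max),
    het_fraction = het_fraction,
    n_line_specific = as.integer(n_line_specific),
    n_gene_deletions = as.integer(n_gene_deletions),
    n_gene_duplications = as.integer(n_gene_duplications),
    n_sv_per_type = as.integer(n_sv_per_type),
    base_depth = base_depth,
    depth_noise_sd = depth_noise_sd,
    depth_bin = as.integer(depth_bin),
    read_length = as.integer(read_length),
    insert_size_mean = insert_size_mean,
    insert_size_sd = insert_size_sd,
    sv_support = as.integer(sv_support),
    forced_effects = forced_effects,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_forced_effects <- function() {
  c(SYNONYMOUS_CODING = 2L, NON_SYNONYMOUS_CODING = 2L, STOP_GAINED = 2L,
    START_LOST = 1L, NON_SYNONYMOUS_START = 1L, STOP_LOST = 1L,
    FRAME_SHIFT = 2L, CODON_INSERTION = 1L, CODON_DELETION = 1L)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chromosomes", "chromosome_length", "n_genes", "n_samples",
              "n_line_specific", "n_gene_deletions", "n_gene_duplications",
              "n_sv_per_type", "indel_length_max", "depth_bin", "read_length",
              "sv_support")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("sim_config: '", f, "' must be a single non-negative count")
  }
  if (length(cfg$gene_length_range) != 2L ||
      any(cfg$gene_length_range <= 0L) ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2])
    stop("sim_config: gene_length_range must be an increasing positive pair")
  if (cfg$chromosome_length < 10L * cfg$gene_length_range[2])
    stop("sim_config: chromosome_length must be at least 10 x the maximum gene length")
  if (cfg$snp_rate < 0 || cfg$indel_rate < 0)
    stop("sim_config: variant rates must be non-negative")
  if (cfg$het_fraction < 0 || cfg$het_fraction > 1)
    stop("sim_config: het_fraction must lie in [0, 1]")
  if (cfg$base_depth < 0 || cfg$depth_noise_sd < 0)
    stop("sim_config: depth parameters must be non-negative")
  if (cfg$insert_size_mean <= 0 || cfg$insert_size_sd < 0)
    stop("sim_config: insert size model must be positive")
  if (length(cfg$forced_effects) &&
      (is.null(names(cfg$forced_effects)) ||
       !all(names(cfg$forced_effects) %in% names(default_forced_effects()))))
    stop("sim_config: forced_effects must be named by known effect classes")
  invisible(cfg)
}
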