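# Shared fixtures, built in code and memoized for the test session.

small_config <- function(seed = 101, ...) {
  args <- list(n_chromosomes = 2, chromosome_length = 3e5, n_genes = 8,
               n_samples = 3, snp_rate = 1e-3, indel_rate = 2e-4,
               n_line_specific = 5, n_gene_deletions = 1,
               n_gene_duplications = 1, n_sv_per_type = 2, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Small simulated panel plus its full analysis.
small_fixture <- function() {
  memo("small", function() {
    p <- simulate_panel(small_config())
    list(p = p, res = run_panel_analysis(p))
  })
}

# Study-scale panel: 5 genotypes, 2 x 1 Mb, 20 genes, ~2,000 SNP and
# ~200 indel union sites, 25 line-specific variants and 3 deletions /
# 3 duplications / 3 SVs per type per genotype.
study_fixture <- function() {
  memo("study", function() {
    p <- simulate_panel(sim_config(seed = 20))
    list(p = p, res = run_panel_analysis(p))
  })
}

# Build a panel_matrix from bare site/genotype specifications.
make_records <- function(chrom, pos, ref, alt, gt, qual = 50, dp = 10,
                         sample = "S") {
  n <- length(pos)
  d <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                  ref = rep_len(ref, n), alt = rep_len(alt, n),
                  qual = rep_len(qual, n), dp = as.integer(rep_len(dp, n)),
                  gt = rep_len(gt, n), sample = rep_len(sample, n))
  classify_variants(d)
}

# Uniform-depth profile covering the given chromosome lengths.
flat_profile <- function(chrom_lengths, depth = 10) {
  prof <- lapply(chrom_lengths, function(L) S4Vectors::Rle(depth, L))
  names(prof) <- names(chrom_lengths)
  prof
}
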