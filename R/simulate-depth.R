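#' Simulate per-sample per-base depth profiles
#'
#' Baseline coverage is piecewise-constant over `depth_bin`-wide bins whose
#' values are drawn from Normal(`base_depth`, `depth_noise_sd`), truncated at
#' zero and rounded to integer read counts; the bin structure emulates the
#' local autocorrelation of real coverage while keeping run-length encoded
#' profiles and bedGraph exports compact. Planted gene deletions zero the gene
#' span except for a small residual (about 4% of bins are left covered, the
#' analog of stray mis-mapped reads), so absence calls are exercised away from
#' the trivial all-zero case; planted duplications double the depth over the
#' gene span. A `control` profile (reference mapped against itself) is emitted
#' with baseline depth everywhere and no events.
#'
#' @param reference Named [Biostrings::DNAStringSet].
#' @param genes [gene_models()] object.
#' @param truth [truth_set()] with the planted `gene_events`.
#' @param config [sim_config()] object.
#' @return Named list (samples plus `"control"`) of depth profiles; each
#'   profile is a named list of per-chromosome [S4Vectors::Rle] vectors.
#' @export
simulate_depth_profiles <- function(reference, genes, truth, config) {
  validate_sim_config(config)
  ev <- truth$gene_events
  if (nrow(ev)) {
    len <- gene_lengths(genes)
    if (any(is.na(len[ev$gene_id])))
      stop("simulate_depth_profiles: gene events reference unknown genes")
  }
  chrom_lengths <- stats::setNames(Biostrings::width(reference),
                                   names(reference))
  samples <- c(panel_sample_names(config), control_sample_name())

  profiles <- lapply(samples, function(s) {
    prof <- lapply(names(chrom_lengths), function(chrom) {
      L <- chrom_lengths[[chrom]]
      n_bins <- ceiling(L / config$depth_bin)
      vals <- pmax(0, round(stats::rnorm(n_bins, config$base_depth,
                                         config$depth_noise_sd)))
      lens <- rep(config$depth_bin, n_bins)
      lens[n_bins] <- L - (n_bins - 1L) * config$depth_bin
      S4Vectors::Rle(as.integer(vals), lens)
    })
    names(prof) <- names(chrom_lengths)
    prof
  })
  names(profiles) <- samples

  resid_frac <- 0.04
  for (i in seq_len(nrow(ev))) {
    s <- ev$sample[i]
    gid <- ev$gene_id[i]
    g <- genes$genes[genes$genes$gene_id == gid, ]
    span <- g$start:g$end
    rle <- profiles[[s]][[g$chrom]]
    vec <- as.integer(S4Vectors::window(rle, g$start, g$end))
    if (ev$event[i] == "deletion") {
      vec[] <- 0L
      n_resid_bins <- max(1L, floor(length(vec) * resid_frac / config$depth_bin))
      bin_starts <- seq(1L, length(vec) - config$depth_bin + 1L,
                        by = config$depth_bin)
      keep <- sample(bin_starts, min(n_resid_bins, length(bin_starts)))
      for (b in keep) vec[b:(b + config$depth_bin - 1L)] <- 3L
    } else {
      vec <- vec * 2L
    }
    new_rle <- c(S4Vectors::window(rle, 1L, g$start - 1L),
                 S4Vectors::Rle(vec),
                 if (g$end < length(rle))
                   S4Vectors::window(rle, g$end + 1L, length(rle)))
    profiles[[s]][[g$chrom]] <- new_rle
  }
  profiles
}

#' Depth at given positions of one sample profile
#'
#' @param profile One sample's profile (named list of per-chromosome Rle).
#' @param chrom Chromosome name.
#' @param pos Integer positions (1-based).
#' @return Integer depths.
#' @export
depth_at <- function(profile, chrom, pos) {
  rle <- profile[[chrom]]
  if (is.null(rle)) stop("depth_at: unknown chromosome ", chrom)
  as.integer(rle[pos])
}

#' Genome-wide median depth of one sample profile
#'
#' Weighted median over the run-length encoded per-base depths.
#' @param profile One sample's profile.
#' @return Numeric scalar median depth.
#' @export
genome_median_depth <- function(profile) {
  vals <- unlist(lapply(profile, S4Vectors::runValue), use.names = FALSE)
  lens <- unlist(lapply(profile, S4Vectors::runLength), use.names = FALSE)
  ord <- order(vals)
  vals <- vals[ord]
  lens <- as.numeric(lens[ord])
  total <- sum(lens)
  cum <- cumsum(lens)
  v1 <- vals[which(cum >= (total + 1) %/% 2)[1]]
  v2 <- vals[which(cum >= (total + 2) %/% 2)[1]]
  (v1 + v2) / 2
}
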