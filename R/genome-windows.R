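#' Windowed variant counts and densities
#'
#' Variant distribution statistics over the union panel: counts and densities
#' per fixed, non-sliding window (default 100 kb, anchored at the start of
#' each pseudomolecule; the last window may be short), per-chromosome SNP
#' density and polymorphism rate per kb, and the indel length spectrum.
#' The polymorphism rate counts SNP plus indel union sites per kb, and all
#' densities count union sites (not summed per-sample calls).
#'
#' @name genome_windows
NULL

#' @rdname genome_windows
#' @param panel A `panel_matrix`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window width in bases (default 100 kb).
#' @return `window_counts()`: data.frame with one row per window per
#'   chromosome: `chrom`, `window_start` (0-based), `window_end` (exclusive),
#'   `n_snps`, `n_insertions`, `n_deletions`, `density` (variants per kb).
#' @export
window_counts <- function(panel, chrom_lengths, window = 100000) {
  if (window < 1) stop("window_counts: window must be >= 1")
  out <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    n_win <- max(1L, ceiling(L / window))
    ws <- as.integer((seq_len(n_win) - 1L) * window)
    we <- pmin(as.integer(ws + window), as.integer(L))
    st <- panel$sites[panel$sites$chrom == chrom, , drop = FALSE]
    wi <- (st$pos - 1L) %/% as.integer(window) + 1L
    cnt <- function(kind) {
      tab <- tabulate(wi[st$kind == kind], nbins = n_win)
      as.integer(tab)
    }
    n_snps <- cnt("SNP")
    n_ins <- cnt("INSERTION")
    n_del <- cnt("DELETION")
    data.frame(chrom = chrom, window_start = ws, window_end = we,
               n_snps = n_snps, n_insertions = n_ins, n_deletions = n_del,
               density = (n_snps + n_ins + n_del) / ((we - ws) / 1000))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @rdname genome_windows
#' @param effects Optional per-site effect annotation (from
#'   [annotate_panel()]) used for the exonic variant density; its `region`
#'   column marks exonic sites.
#' @return `chromosome_density()`: data.frame with one row per chromosome:
#'   `chrom`, `length`, `n_snps`, `n_indels`, `snp_density`,
#'   `polymorphism_rate` and `exon_variant_density` (all per kb; the exonic
#'   column is `NA` without `effects`).
#' @export
chromosome_density <- function(panel, chrom_lengths, effects = NULL) {
  if (any(chrom_lengths <= 0)) stop("chromosome_density: zero-length chromosome")
  out <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    sel <- panel$sites$chrom == chrom
    n_snps <- sum(sel & panel$sites$kind == "SNP")
    n_indels <- sum(sel & panel$sites$kind %in% c("INSERTION", "DELETION"))
    exon_d <- NA_real_
    if (!is.null(effects))
      exon_d <- sum(sel & effects$region == "EXON") / (L / 1000)
    data.frame(chrom = chrom, length = L, n_snps = n_snps,
               n_indels = n_indels,
               snp_density = n_snps / (L / 1000),
               polymorphism_rate = (n_snps + n_indels) / (L / 1000),
               exon_variant_density = exon_d)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @rdname genome_windows
#' @param max_len Longest indel length tracked (default 58).
#' @return `indel_spectrum()`: data.frame with one row per length
#'   `1:max_len`: `length`, `n_insertions`, `n_deletions`.
#' @export
indel_spectrum <- function(panel, max_len = 58) {
  st <- panel$sites
  ins <- tabulate(st$len[st$kind == "INSERTION"], nbins = max_len)
  del <- tabulate(st$len[st$kind == "DELETION"], nbins = max_len)
  data.frame(length = seq_len(max_len),
             n_insertions = as.integer(ins),
             n_deletions = as.integer(del))
}
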