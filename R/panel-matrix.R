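#' Merge filtered per-sample calls into a variants-by-samples panel
#'
#' Sites are the union across samples of (chrom, pos, ref, alt) after
#' filtering and classification; each (site, sample) cell carries exactly one
#' genotype state. A sample without a record at a union site is called
#' homozygous-reference when its depth profile covers the site at
#' `min_depth` or more reads, and missing otherwise — depth is the only
#' available confidence signal for a reference call, and the line-specific
#' rule requires confident reference calls in every other genotype. When no
#' depth profiles are supplied, absent calls default to homozygous-reference.
#'
#' @param per_sample Named list of classified call data.frames
#'   (from [filter_sample_calls()]`$kept`; must have `kind` and `len`
#'   columns).
#' @param depth Optional named list of depth profiles (per-chromosome
#'   [S4Vectors::Rle]), one per sample, used by the absence-of-call policy.
#' @param min_depth Depth needed to call an uncovered site
#'   homozygous-reference.
#' @return An object of class `panel_matrix`: list with `sites` (data.frame
#'   `chrom`, `pos`, `ref`, `alt`, `kind`, `len`), `geno` (integer matrix,
#'   sites x samples: 0 hom_ref, 1 het, 2 hom_alt, NA missing) and `samples`.
#' @export
build_panel <- function(per_sample, depth = NULL, min_depth = 5) {
  samples <- names(per_sample)
  if (is.null(samples) || any(samples == ""))
    stop("build_panel: per_sample must be a named list")
  all_rec <- do.call(rbind, lapply(samples, function(s) {
    d <- per_sample[[s]]
    d$sample <- rep(s, nrow(d))
    d[, c("chrom", "pos", "ref", "alt", "kind", "len", "gt", "sample")]
  }))
  if (is.null(all_rec) || nrow(all_rec) == 0L) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        kind = character(0), len = integer(0))
    geno <- matrix(integer(0), nrow = 0, ncol = length(samples),
                   dimnames = list(NULL, samples))
    return(structure(list(sites = sites, geno = geno, samples = samples),
                     class = "panel_matrix"))
  }

  key <- paste(all_rec$chrom, all_rec$pos, all_rec$ref, all_rec$alt,
               sep = "\r")
  sites <- all_rec[!duplicated(key), c("chrom", "pos", "ref", "alt",
                                       "kind", "len")]
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL

  # the reference context must agree where sites share an anchor position
  anchor <- substr(sites$ref, 1L, 1L)
  pk <- paste(sites$chrom, sites$pos, sep = "\r")
  if (any(tapply(anchor, pk, function(a) length(unique(a))) > 1L))
    stop("build_panel: conflicting reference alleles at one position")

  site_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = "\r")
  gt_code <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  geno <- matrix(NA_integer_, nrow = nrow(sites), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (s in samples) {
    rec <- all_rec[all_rec$sample == s, , drop = FALSE]
    ri <- match(paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = "\r"),
                site_key)
    geno[ri, s] <- gt_code[rec$gt]
    absent <- which(is.na(geno[, s]))
    if (length(absent)) {
      if (is.null(depth)) {
        geno[absent, s] <- 0L
      } else {
        prof <- depth[[s]]
        if (is.null(prof))
          stop("build_panel: no depth profile for sample ", s)
        for (chrom in unique(sites$chrom[absent])) {
          ii <- absent[sites$chrom[absent] == chrom]
          dp <- depth_at(prof, chrom, sites$pos[ii])
          geno[ii, s] <- ifelse(dp >= min_depth, 0L, NA_integer_)
        }
      }
    }
  }
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "panel_matrix")
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat("panel_matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples (", sum(x$sites$kind == "SNP"), "SNPs )\n")
  invisible(x)
}

check_sample <- function(panel, sample) {
  if (!sample %in% panel$samples)
    stop("unknown sample: ", sample)
}

#' Zygosity counts and heterozygosity rate for one sample
#'
#' Counts homozygous-alternate and heterozygous SNP calls of the sample; the
#' heterozygosity rate is het / (het + hom), 0 when the sample has no SNP
#' calls.
#' @param panel A `panel_matrix`.
#' @param sample Sample name.
#' @return List with `n_hom`, `n_het`, `heterozygosity_rate`.
#' @export
zygosity_counts <- function(panel, sample) {
  check_sample(panel, sample)
  g <- panel$geno[panel$sites$kind == "SNP", sample]
  n_hom <- sum(g == 2L, na.rm = TRUE)
  n_het <- sum(g == 1L, na.rm = TRUE)
  rate <- if (n_hom + n_het == 0L) 0 else n_het / (n_het + n_hom)
  list(n_hom = n_hom, n_het = n_het, heterozygosity_rate = rate)
}

#' Pairwise SNP count between two samples
#'
#' Number of SNP sites at which the two genotypes disagree and neither is
#' missing.
#' @param panel A `panel_matrix`.
#' @param a,b Two distinct sample names.
#' @return Integer count.
#' @export
pairwise_snp_count <- function(panel, a, b) {
  check_sample(panel, a)
  check_sample(panel, b)
  if (a == b) stop("pairwise_snp_count: samples must differ")
  snp <- panel$sites$kind == "SNP"
  ga <- panel$geno[snp, a]
  gb <- panel$geno[snp, b]
  sum(ga != gb & !is.na(ga) & !is.na(gb), na.rm = TRUE)
}

#' Line-specific variants per sample
#'
#' A site is line-specific for a sample when that sample carries the
#' alternate allele (het or hom-alt) and every other sample is confidently
#' homozygous-reference; a missing call in any other sample disqualifies the
#' site.
#' @param panel A `panel_matrix`.
#' @return Named list (per sample) of data.frames with the line-specific
#'   `snps` and `indels` site tables.
#' @export
line_specific_variants <- function(panel) {
  g <- panel$geno
  carrier <- !is.na(g) & g >= 1L
  homref <- !is.na(g) & g == 0L
  n_carrier <- rowSums(carrier)
  all_others_ref <- rowSums(homref) == length(panel$samples) - 1L
  is_ls <- n_carrier == 1L & all_others_ref
  out <- lapply(panel$samples, function(s) {
    sel <- is_ls & carrier[, s]
    st <- panel$sites[sel, , drop = FALSE]
    list(snps = st[st$kind == "SNP", , drop = FALSE],
         indels = st[st$kind %in% c("INSERTION", "DELETION"), , drop = FALSE])
  })
  names(out) <- panel$samples
  out
}

#' Insertion/deletion ratio for one sample
#'
#' @param panel A `panel_matrix`.
#' @param sample Sample name.
#' @return Insertions divided by deletions over the sample's non-reference
#'   calls, or `NA` when the sample has no deletions.
#' @export
indel_ratio <- function(panel, sample) {
  check_sample(panel, sample)
  g <- panel$geno[, sample]
  nonref <- !is.na(g) & g >= 1L
  n_ins <- sum(nonref & panel$sites$kind == "INSERTION")
  n_del <- sum(nonref & panel$sites$kind == "DELETION")
  if (n_del == 0L) return(NA_real_)
  n_ins / n_del
}

#' Per-sample summary of panel counts
#'
#' @param panel A `panel_matrix`.
#' @return data.frame with one row per sample: SNP/insertion/deletion call
#'   counts, line-specific counts, zygosity counts, heterozygosity rate and
#'   indel ratio.
#' @export
sample_summary <- function(panel) {
  ls <- line_specific_variants(panel)
  rows <- lapply(panel$samples, function(s) {
    g <- panel$geno[, s]
    nonref <- !is.na(g) & g >= 1L
    zy <- zygosity_counts(panel, s)
    data.frame(
      sample = s,
      n_snps = sum(nonref & panel$sites$kind == "SNP"),
      n_insertions = sum(nonref & panel$sites$kind == "INSERTION"),
      n_deletions = sum(nonref & panel$sites$kind == "DELETION"),
      ls_snps = nrow(ls[[s]]$snps),
      ls_indels = nrow(ls[[s]]$indels),
      n_hom = zy$n_hom, n_het = zy$n_het,
      heterozygosity_rate = zy$heterozygosity_rate,
      indel_ratio = indel_ratio(panel, s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise SNP count matrix over all samples
#' @param panel A `panel_matrix`.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
pairwise_snp_matrix <- function(panel) {
  n <- length(panel$samples)
  m <- matrix(0L, n, n, dimnames = list(panel$samples, panel$samples))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairwise_snp_count(panel, panel$samples[i],
                                             panel$samples[j])
  }
  m
}
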