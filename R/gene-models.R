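#' Gene-model container
#'
#' Holds a one-transcript-per-gene annotation: gene spans, exon intervals and
#' CDS intervals with phase. All coordinates are 1-based inclusive. Exons per
#' gene are non-overlapping and sorted; the CDS is contained in the exons and
#' its total length is divisible by three; translated on the gene strand it
#' starts with ATG and ends with a stop codon.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `rank`.
#' @param cds data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `rank`, `phase`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds) {
  norm <- function(df) {
    df <- as.data.frame(df)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  gm <- list(genes = norm(genes), exons = norm(exons), cds = norm(cds))
  class(gm) <- "gene_models"
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df)))
      stop("gene_models: ", what, " table must have columns ",
           paste(cols, collapse = ", "))
  }
  need(gm$genes, c("gene_id", "chrom", "strand", "start", "end"), "genes")
  need(gm$exons, c("gene_id", "chrom", "start", "end", "rank"), "exons")
  need(gm$cds, c("gene_id", "chrom", "start", "end", "rank", "phase"), "cds")
  if (nrow(gm$genes)) {
    if (!all(gm$genes$strand %in% c("+", "-")))
      stop("gene_models: strand must be '+' or '-'")
    if (any(gm$genes$start > gm$genes$end))
      stop("gene_models: gene start must not exceed end")
    cds_len <- tapply(gm$cds$end - gm$cds$start + 1L, gm$cds$gene_id, sum)
    if (any(cds_len %% 3L != 0L))
      stop("gene_models: total CDS length must be divisible by 3")
  }
  invisible(gm)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      nrow(x$exons), "exons,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}

#' Gene lengths in bases
#' @param gm A `gene_models` object.
#' @return Named integer vector of gene span lengths.
#' @export
gene_lengths <- function(gm) {
  stats::setNames(gm$genes$end - gm$genes$start + 1L, gm$genes$gene_id)
}

# Genomic positions of the CDS of one gene in translation (5'->3') order.
cds_genomic_positions <- function(gm, gene_id) {
  seg <- gm$cds[gm$cds$gene_id == gene_id, , drop = FALSE]
  if (!nrow(seg)) return(integer(0))
  seg <- seg[order(seg$start), , drop = FALSE]
  pos <- unlist(Map(seq.int, seg$start, seg$end), use.names = FALSE)
  strand <- gm$genes$strand[match(gene_id, gm$genes$gene_id)]
  if (strand == "-") pos <- rev(pos)
  as.integer(pos)
}

# Coding sequence of one gene, read 5'->3' on the gene strand.
cds_coding_seq <- function(gm, gene_id, reference) {
  pos <- cds_genomic_positions(gm, gene_id)
  if (!length(pos)) return("")
  chrom <- gm$genes$chrom[match(gene_id, gm$genes$gene_id)]
  strand <- gm$genes$strand[match(gene_id, gm$genes$gene_id)]
  bases <- chrom_bases(reference, chrom, sort(pos))
  s <- paste(bases, collapse = "")
  if (strand == "-") s <- revcomp(s) else s
}

# Extract single bases at positions of one chromosome as a character vector.
chrom_bases <- function(reference, chrom, pos) {
  as.character(Biostrings::extractAt(reference[[chrom]],
                                     IRanges::IRanges(pos, pos)))
}

# Extract one substring [start, end] of a chromosome.
chrom_substr <- function(reference, chrom, start, end) {
  as.character(Biostrings::subseq(reference[[chrom]], start, end))
}
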