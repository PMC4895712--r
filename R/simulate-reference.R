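#' Generate a synthetic reference genome with gene models
#'
#' Builds `n_chromosomes` pseudomolecules (named `Ca1`, `Ca2`, ...) of uniform
#' random A/C/G/T sequence and packs `n_genes` non-overlapping gene models onto
#' them, alternating strands. Each gene has one or two exons (two-exon genes
#' carry a short intron), a CDS whose total length is divisible by three, an
#' ATG initiator and a terminal stop codon on its own strand, and no internal
#' in-frame stop codon; the CDS bases are written into the chromosome sequence
#' so that annotation against the emitted reference is exact.
#'
#' Seeds the RNG from `config$seed`; the downstream simulators consume the
#' stream that this function leaves behind, so a fixed seed and call order
#' reproduce the whole panel byte for byte.
#'
#' @param config A [sim_config()] object.
#' @return A list with `reference` (a named [Biostrings::DNAStringSet]) and
#'   `genes` (a [gene_models()] object).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  L <- config$chromosome_length
  chrom_names <- paste0("Ca", seq_len(n_chr))

  chars <- lapply(seq_len(n_chr), function(i) random_bases(L))

  genes_df <- data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0))
  exons_df <- data.frame(gene_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         rank = integer(0))
  cds_df <- data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       rank = integer(0), phase = integer(0))

  if (config$n_genes > 0L) {
    chrom_of <- rep(seq_len(n_chr), length.out = config$n_genes)
    margin <- 2000L
    gap_min <- 200L
    for (ci in seq_len(n_chr)) {
      idx <- which(chrom_of == ci)
      k <- length(idx)
      if (!k) next
      span_len <- sample(seq(config$gene_length_range[1],
                             config$gene_length_range[2]), k, replace = TRUE)
      slack <- L - 2L * margin - sum(span_len) - (k + 1L) * gap_min
      if (slack < 0L)
        stop("generate_reference: genes cannot be packed without overlap on ",
             chrom_names[ci])
      extra <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1L)))
      gaps <- gap_min + extra
      starts <- margin + cumsum(gaps[seq_len(k)]) + cumsum(c(0L, span_len[-k]))
      for (j in seq_len(k)) {
        g <- idx[j]
        gid <- sprintf("gene%03d", g)
        strand <- if (g %% 2L == 1L) "+" else "-"
        built <- build_gene(span_len[j], strand)
        gstart <- starts[j]
        gend <- gstart + built$span_len - 1L
        genes_df <- rbind(genes_df, data.frame(
          gene_id = gid, chrom = chrom_names[ci], strand = strand,
          start = gstart, end = gend))
        ex_start <- gstart + built$exon_off
        ex_end <- ex_start + built$exon_len - 1L
        n_ex <- length(ex_start)
        exons_df <- rbind(exons_df, data.frame(
          gene_id = gid, chrom = chrom_names[ci],
          start = ex_start, end = ex_end, rank = seq_len(n_ex)))
        cds_df <- rbind(cds_df, data.frame(
          gene_id = gid, chrom = chrom_names[ci],
          start = ex_start, end = ex_end, rank = seq_len(n_ex),
          phase = built$phase))
        # write CDS bases into the chromosome, genomic order
        seq_chars <- strsplit(built$genomic_seq, "")[[1]]
        off <- 0L
        for (e in seq_len(n_ex)) {
          w <- built$exon_len[e]
          chars[[ci]][ex_start[e]:ex_end[e]] <- seq_chars[(off + 1L):(off + w)]
          off <- off + w
        }
      }
    }
  }

  reference <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
  names(reference) <- chrom_names
  list(reference = reference,
       genes = gene_models(genes_df, exons_df, cds_df))
}

# Plan the internal structure of one gene: exon offsets/lengths within the
# span, GFF3 phases, and the genomic-orientation CDS sequence to be written
# into the chromosome. Two-exon genes get an intron of 120-200 bp.
build_gene <- function(span_len, strand) {
  n_ex <- sample(1:2, 1)
  intron_len <- if (n_ex == 2L) sample(120:200, 1) else 0L
  cds_len <- span_len - intron_len
  cds_len <- cds_len - (cds_len %% 3L)
  if (cds_len < 30L)
    stop("build_gene: gene span too short for a coding sequence")
  span_len <- cds_len + intron_len

  n_cod <- cds_len %/% 3L
  body <- sample(setdiff(sense_codons(), "ATG"), n_cod - 2L, replace = TRUE)
  codons <- c("ATG", body, sample(stop_codons(), 1))
  coding <- paste(codons, collapse = "")
  genomic <- if (strand == "+") coding else revcomp(coding)

  if (n_ex == 1L) {
    exon_len <- cds_len
    exon_off <- 0L
    phase <- 0L
  } else {
    e1 <- sample(seq(30L, cds_len - 30L), 1)
    exon_len <- c(e1, cds_len - e1)
    exon_off <- c(0L, e1 + intron_len)
    # phase: bases to skip at the 5' (translation) start of each piece
    if (strand == "+") {
      phase <- c(0L, (3L - exon_len[1] %% 3L) %% 3L)
    } else {
      phase <- c((3L - exon_len[2] %% 3L) %% 3L, 0L)
    }
  }
  list(span_len = span_len, exon_off = as.integer(exon_off),
       exon_len = as.integer(exon_len), phase = as.integer(phase),
       genomic_seq = genomic)
}
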