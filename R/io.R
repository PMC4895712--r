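#' Read and write panel files
#'
#' The on-disk layout written by [write_panel()] is:
#' ```
#' <dir>/reference.fa          reference genome (FASTA)
#' <dir>/genes.gff3            gene models (GFF3: gene/mRNA/exon/CDS + phase)
#' <dir>/vcf/<sample>.vcf      per-sample calls (VCF v4.2, QUAL + GT:DP)
#' <dir>/depth/<sample>.bedGraph  per-base depth (0-based half-open)
#' <dir>/pairs/<sample>.bedpe  discordant pairs (0-based half-open)
#' <dir>/truth/*.tsv           planted truth tables
#' ```
#' VCF and GFF3 are 1-based inclusive; bedGraph and BEDPE are 0-based
#' half-open (see [to_zero_based()]). Reading a written panel back reproduces
#' the in-memory objects.
#'
#' @param panel A `sim_panel` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `write_panel()` returns `dir` invisibly; `read_panel()` returns a
#'   list with the same structure as a `sim_panel` (minus `config`).
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_panel <- function(panel, dir) {
  for (d in file.path(dir, c("", "vcf", "depth", "pairs", "truth")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("write_panel: cannot create directory ", dir)

  Biostrings::writeXStringSet(panel$reference, file.path(dir, "reference.fa"))
  write_gff3(panel$genes, file.path(dir, "genes.gff3"))
  contigs <- stats::setNames(Biostrings::width(panel$reference),
                             names(panel$reference))
  for (s in names(panel$calls))
    write_vcf(panel$calls[[s]], file.path(dir, "vcf", paste0(s, ".vcf")),
              sample = s, contigs = contigs)
  for (s in names(panel$depth))
    write_bedgraph(panel$depth[[s]],
                   file.path(dir, "depth", paste0(s, ".bedGraph")))
  for (s in names(panel$pairs))
    write_bedpe(panel$pairs[[s]],
                file.path(dir, "pairs", paste0(s, ".bedpe")))
  data.table::fwrite(panel$truth$variants,
                     file.path(dir, "truth", "variants.tsv"), sep = "\t",
                     na = "NA")
  data.table::fwrite(panel$truth$gene_events,
                     file.path(dir, "truth", "gene_events.tsv"), sep = "\t")
  data.table::fwrite(panel$truth$sv_events,
                     file.path(dir, "truth", "sv_events.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname panel_io
#' @export
read_panel <- function(dir) {
  reference <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  genes <- read_gff3(file.path(dir, "genes.gff3"))
  chrom_lengths <- stats::setNames(Biostrings::width(reference),
                                   names(reference))

  vcfs <- sort(list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                          full.names = TRUE))
  calls <- lapply(vcfs, read_vcf)
  names(calls) <- sub("\\.vcf$", "", basename(vcfs))

  bgs <- sort(list.files(file.path(dir, "depth"), pattern = "\\.bedGraph$",
                         full.names = TRUE))
  depth <- lapply(bgs, read_bedgraph, chrom_lengths = chrom_lengths)
  names(depth) <- sub("\\.bedGraph$", "", basename(bgs))

  bps <- sort(list.files(file.path(dir, "pairs"), pattern = "\\.bedpe$",
                         full.names = TRUE))
  pairs <- lapply(bps, function(f)
    read_bedpe(f, sample = sub("\\.bedpe$", "", basename(f))))
  names(pairs) <- sub("\\.bedpe$", "", basename(bps))

  truth <- truth_set(
    read_tsv_df(file.path(dir, "truth", "variants.tsv")),
    read_tsv_df(file.path(dir, "truth", "gene_events.tsv")),
    read_tsv_df(file.path(dir, "truth", "sv_events.tsv")))
  list(reference = reference, genes = genes, calls = calls,
       depth = depth, pairs = pairs, truth = truth)
}

read_tsv_df <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

# --- VCF ----------------------------------------------------------------

gt_to_vcf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
vcf_to_gt <- stats::setNames(names(gt_to_vcf), gt_to_vcf)

#' Write a single-sample VCF v4.2
#'
#' @param records Call data.frame (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `dp`, `gt`).
#' @param path Output file.
#' @param sample Sample name for the genotype column.
#' @param contigs Named vector of chromosome lengths for `##contig` lines.
#' @export
write_vcf <- function(records, path, sample, contigs) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panelvar",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"))
  body <- character(0)
  if (nrow(records)) {
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  sprintf("%.1f", records$qual), "PASS", ".", "GT:DP",
                  paste0(gt_to_vcf[records$gt], ":", records$dp),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a single-sample VCF into a call data.frame
#'
#' @param path VCF file.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `dp`, `gt`, `sample`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  sample <- colnames(v@gt)[2]
  if (nrow(v@fix) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), dp = integer(0),
                      gt = character(0), sample = character(0)))
  }
  gt <- vcfR::extract.gt(v, "GT")[, 1]
  dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
  d <- data.frame(chrom = v@fix[, "CHROM"],
                  pos = as.integer(v@fix[, "POS"]),
                  ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                  qual = as.numeric(v@fix[, "QUAL"]),
                  dp = dp,
                  gt = unname(vcf_to_gt[gt]),
                  sample = sample)
  rownames(d) <- NULL
  d
}

# --- GFF3 ---------------------------------------------------------------

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (one transcript per gene) with
#' CDS phase.
#' @param genes A [gene_models()] object.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  g <- genes$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      paste(g$chrom[i], "panelvar", "gene", g$start[i], g$end[i], ".",
            g$strand[i], ".", sprintf("ID=%s", gid), sep = "\t"),
      paste(g$chrom[i], "panelvar", "mRNA", g$start[i], g$end[i], ".",
            g$strand[i], ".", sprintf("ID=%s;Parent=%s", tid, gid),
            sep = "\t"))
    ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$rank), , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, paste(ex$chrom[j], "panelvar", "exon", ex$start[j],
                              ex$end[j], ".", g$strand[i], ".",
                              sprintf("ID=%s.exon%d;Parent=%s", gid,
                                      ex$rank[j], tid), sep = "\t"))
    cd <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    cd <- cd[order(cd$rank), , drop = FALSE]
    for (j in seq_len(nrow(cd)))
      lines <- c(lines, paste(cd$chrom[j], "panelvar", "CDS", cd$start[j],
                              cd$end[j], ".", g$strand[i], cd$phase[j],
                              sprintf("ID=%s.cds%d;Parent=%s", gid,
                                      cd$rank[j], tid), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @return A [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent1 <- vapply(md$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  gene_of_tx <- sub("\\.t1$", "", parent1)

  is_gene <- md$type == "gene"
  genes <- data.frame(
    gene_id = md$ID[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene])

  pick <- function(type, with_phase = FALSE) {
    sel <- md$type == type
    d <- data.frame(
      gene_id = gene_of_tx[sel],
      chrom = as.character(GenomicRanges::seqnames(gr))[sel],
      start = GenomicRanges::start(gr)[sel],
      end = GenomicRanges::end(gr)[sel])
    if (with_phase) {
      ph <- md$phase[sel]
      d$phase <- as.integer(as.character(ph))
    }
    d <- d[order(d$gene_id, d$start), , drop = FALSE]
    d$rank <- stats::ave(seq_len(nrow(d)), d$gene_id,
                         FUN = seq_along)
    rownames(d) <- NULL
    d
  }
  exons <- pick("exon")
  cds <- pick("CDS", with_phase = TRUE)
  exons <- exons[, c("gene_id", "chrom", "start", "end", "rank")]
  cds <- cds[, c("gene_id", "chrom", "start", "end", "rank", "phase")]
  gene_models(genes, exons, cds)
}

# --- bedGraph -----------------------------------------------------------

#' Write a depth profile as bedGraph
#'
#' Intervals are 0-based half-open and tile each chromosome exactly.
#' @param profile Named list of per-chromosome [S4Vectors::Rle] depths.
#' @param path Output file.
#' @export
write_bedgraph <- function(profile, path) {
  parts <- lapply(names(profile), function(chrom) {
    rle <- profile[[chrom]]
    lens <- S4Vectors::runLength(rle)
    vals <- S4Vectors::runValue(rle)
    end0 <- cumsum(as.numeric(lens))
    start0 <- end0 - as.numeric(lens)
    data.table::data.table(chrom = chrom, start0 = as.integer(start0),
                           end0 = as.integer(end0), depth = vals)
  })
  data.table::fwrite(data.table::rbindlist(parts), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph depth profile
#'
#' @param path bedGraph file.
#' @param chrom_lengths Named vector of chromosome lengths; intervals must
#'   tile `[0, length)` per chromosome.
#' @return Named list of per-chromosome [S4Vectors::Rle] depths.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  d <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start0", "end0", "depth"))
  prof <- lapply(names(chrom_lengths), function(chrom) {
    dc <- d[d$chrom == chrom, ]
    dc <- dc[order(dc$start0), ]
    L <- chrom_lengths[[chrom]]
    if (nrow(dc) == 0L) return(S4Vectors::Rle(0L, L))
    if (dc$start0[1] != 0L || dc$end0[nrow(dc)] != L ||
        (nrow(dc) > 1L && any(dc$start0[-1] != dc$end0[-nrow(dc)])))
      stop("read_bedgraph: intervals do not tile [0, ", L, ") on ", chrom)
    S4Vectors::Rle(as.integer(dc$depth), dc$end0 - dc$start0)
  })
  names(prof) <- names(chrom_lengths)
  prof
}

# --- BEDPE --------------------------------------------------------------

bedpe_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                "name", "mapq", "strand1", "strand2")

#' Write discordant pairs as a BEDPE-like table
#' @param pairs Pair data.frame (see [simulate_discordant_pairs()]).
#' @param path Output file.
#' @export
write_bedpe <- function(pairs, path) {
  data.table::fwrite(pairs[, bedpe_cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE-like table of discordant pairs
#' @param path BEDPE file.
#' @param sample Sample name to attach.
#' @return Pair data.frame.
#' @export
read_bedpe <- function(path, sample) {
  if (file.size(path) == 0L) {
    d <- data.frame(matrix(nrow = 0, ncol = length(bedpe_cols)))
    names(d) <- bedpe_cols
    d$chrom1 <- character(0); d$start1 <- integer(0); d$end1 <- integer(0)
    d$chrom2 <- character(0); d$start2 <- integer(0); d$end2 <- integer(0)
    d$name <- character(0); d$mapq <- integer(0)
    d$strand1 <- character(0); d$strand2 <- character(0)
    d$sample <- character(0)
    return(d)
  }
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE,
                                       col.names = bedpe_cols))
  d$sample <- sample
  d
}
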