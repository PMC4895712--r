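#' Codon-level variant effect annotation
#'
#' Classifies each union site against one-transcript gene models. The region
#' is EXON when the variant anchor lies in a CDS, OTHER for untranslated exon
#' positions and for indels that span a CDS boundary, INTRON within a gene
#' span outside its exons, and INTERGENIC elsewhere. For coding SNPs the
#' affected codon is rebuilt on the coding strand (reverse-complemented for
#' minus-strand genes) and the reference and alternate codons are translated
#' with the standard genetic code:
#'
#' * same amino acid: `SYNONYMOUS_CODING` (`SYNONYMOUS_STOP` when a stop
#'   codon stays a stop);
#' * different amino acid: `NON_SYNONYMOUS_CODING`;
#' * sense codon to stop: `STOP_GAINED`; terminal stop to sense: `STOP_LOST`;
#' * at the initiator ATG: a change into an alternative start codon
#'   (CTG/TTG/GTG) is `NON_SYNONYMOUS_START`, any other change is
#'   `START_LOST`.
#'
#' Coding indels are `FRAME_SHIFT` when their length is not a multiple of
#' three, otherwise `CODON_INSERTION` / `CODON_DELETION`.
#'
#' A mismatch between a site's reference allele and the reference genome is
#' an error: it guards against coordinate bugs.
#'
#' @name effect_annotation
NULL

effect_levels <- function() {
  c("SYNONYMOUS_CODING", "SYNONYMOUS_STOP", "NON_SYNONYMOUS_CODING",
    "NON_SYNONYMOUS_START", "START_LOST", "STOP_GAINED", "STOP_LOST",
    "FRAME_SHIFT", "CODON_INSERTION", "CODON_DELETION", "NONE")
}

# Classify a single-codon substitution given its position in the CDS.
classify_codon_change <- function(ref_codon, alt_codon, codon_index,
                                  n_codons) {
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])
  if (codon_index == 1L) {
    if (alt_codon == ref_codon) return("SYNONYMOUS_CODING")
    if (alt_codon %in% alt_start_codons()) return("NON_SYNONYMOUS_START")
    return("START_LOST")
  }
  if (ref_aa == "*") {
    if (alt_aa == "*") return("SYNONYMOUS_STOP")
    return("STOP_LOST")
  }
  if (alt_aa == "*") return("STOP_GAINED")
  if (ref_aa == alt_aa) return("SYNONYMOUS_CODING")
  "NON_SYNONYMOUS_CODING"
}

# Per-gene lookup tables used by the annotators.
gene_index <- function(genes, reference) {
  idx <- lapply(genes$genes$gene_id, function(gid) {
    posvec <- cds_genomic_positions(genes, gid)
    list(gene_id = gid,
         strand = genes$genes$strand[match(gid, genes$genes$gene_id)],
         chrom = genes$genes$chrom[match(gid, genes$genes$gene_id)],
         posvec = posvec,
         pos_index = stats::setNames(seq_along(posvec), posvec),
         coding = cds_coding_seq(genes, gid, reference),
         n_codons = length(posvec) %/% 3L)
  })
  names(idx) <- genes$genes$gene_id
  idx
}

#' Locate variants relative to gene models
#'
#' @param sites data.frame with `chrom` and `pos` (anchor positions).
#' @param genes A [gene_models()] object.
#' @return data.frame with `region` (`EXON`, `OTHER`, `INTRON`,
#'   `INTERGENIC`) and `gene_id` (`NA` for intergenic sites), row-aligned
#'   with `sites`.
#' @export
locate_variants <- function(sites, genes) {
  n <- nrow(sites)
  region <- rep("INTERGENIC", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L || nrow(genes$genes) == 0L)
    return(data.frame(region = region, gene_id = gene_id))

  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  gr_gene <- GenomicRanges::GRanges(
    genes$genes$chrom, IRanges::IRanges(genes$genes$start, genes$genes$end))
  gr_exon <- GenomicRanges::GRanges(
    genes$exons$chrom, IRanges::IRanges(genes$exons$start, genes$exons$end))
  gr_cds <- GenomicRanges::GRanges(
    genes$cds$chrom, IRanges::IRanges(genes$cds$start, genes$cds$end))

  hg <- GenomicRanges::findOverlaps(q, gr_gene, select = "first")
  in_gene <- !is.na(hg)
  region[in_gene] <- "INTRON"
  gene_id[in_gene] <- genes$genes$gene_id[hg[in_gene]]

  he <- GenomicRanges::findOverlaps(q, gr_exon, select = "first")
  region[!is.na(he)] <- "OTHER"
  hc <- GenomicRanges::findOverlaps(q, gr_cds, select = "first")
  region[!is.na(hc)] <- "EXON"

  data.frame(region = region, gene_id = gene_id)
}

#' Annotate one coding SNP
#'
#' @param chrom,pos,ref,alt The variant (single-base alleles).
#' @param gidx One entry of the internal gene index (gene the variant lies
#'   in).
#' @param reference Named [Biostrings::DNAStringSet].
#' @return Effect class string.
#' @keywords internal
annotate_snp_one <- function(chrom, pos, ref, alt, gidx, reference) {
  ref_genome <- chrom_bases(reference, chrom, pos)
  if (ref_genome != ref)
    stop("annotate_snp: reference allele mismatch at ", chrom, ":", pos,
         " (genome ", ref_genome, ", record ", ref, ")")
  i <- unname(gidx$pos_index[as.character(pos)])
  if (is.na(i)) return("NONE")
  ci <- (i - 1L) %/% 3L + 1L
  cp <- (i - 1L) %% 3L + 1L
  ref_codon <- substr(gidx$coding, (ci - 1L) * 3L + 1L, ci * 3L)
  alt_base <- if (gidx$strand == "+") alt else comp_base(alt)
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- alt_base
  classify_codon_change(ref_codon, alt_codon, ci, gidx$n_codons)
}

#' Annotate all panel sites against gene models
#'
#' @param panel A `panel_matrix` (or any object with a `sites` data.frame
#'   holding `chrom`, `pos`, `ref`, `alt`, `kind`, `len`).
#' @param genes A [gene_models()] object.
#' @param reference Named [Biostrings::DNAStringSet].
#' @return data.frame row-aligned with `panel$sites`: `region`, `effect`,
#'   `gene_id`. Every coding site receives exactly one effect class;
#'   non-exonic sites have effect `NONE`.
#' @export
annotate_panel <- function(panel, genes, reference) {
  sites <- panel$sites
  loc <- locate_variants(sites, genes)
  effect <- rep("NONE", nrow(sites))
  gidx_all <- gene_index(genes, reference)

  for (i in which(loc$region == "EXON")) {
    gidx <- gidx_all[[loc$gene_id[i]]]
    if (sites$kind[i] == "SNP") {
      effect[i] <- annotate_snp_one(sites$chrom[i], sites$pos[i],
                                    sites$ref[i], sites$alt[i],
                                    gidx, reference)
    } else if (sites$kind[i] %in% c("INSERTION", "DELETION")) {
      span_in_cds <- indel_within_cds(sites$pos[i], sites$len[i],
                                      sites$kind[i], gidx)
      if (!span_in_cds) {
        loc$region[i] <- "OTHER"
      } else if (sites$len[i] %% 3L != 0L) {
        effect[i] <- "FRAME_SHIFT"
      } else {
        effect[i] <- if (sites$kind[i] == "INSERTION") "CODON_INSERTION"
                     else "CODON_DELETION"
      }
    } else {
      loc$region[i] <- "OTHER"
    }
  }
  data.frame(region = loc$region, effect = effect, gene_id = loc$gene_id)
}

# TRUE when the bases an indel touches lie entirely inside the gene's CDS:
# for a deletion the deleted bases (anchor+1 .. anchor+len), for an
# insertion the two bases flanking the insertion point.
indel_within_cds <- function(pos, len, kind, gidx) {
  touched <- if (kind == "DELETION") (pos + 1L):(pos + len)
             else c(pos, pos + 1L)
  all(as.character(touched) %in% names(gidx$pos_index))
}

#' Summaries of effect annotation
#'
#' Genome totals split the coding SNP classes the way variant reports
#' conventionally do: mis-sense (non-synonymous coding + non-synonymous
#' start), non-sense (stop gained) and silent (synonymous coding +
#' synonymous stop). Per-sample rows count the sample's non-reference calls
#' per region and effect class.
#'
#' @param panel A `panel_matrix`.
#' @param effects Annotation from [annotate_panel()].
#' @return List with `genome` (named totals incl. `mis_sense`, `non_sense`,
#'   `silent`) and `per_sample` (data.frame, one row per sample).
#' @export
summarize_effects <- function(panel, effects) {
  eff <- factor(effects$effect, levels = effect_levels())
  reg <- factor(effects$region,
                levels = c("INTERGENIC", "INTRON", "EXON", "OTHER"))
  genome <- c(table(reg), table(eff))
  genome <- c(genome,
              mis_sense = sum(effects$effect %in%
                                c("NON_SYNONYMOUS_CODING",
                                  "NON_SYNONYMOUS_START")),
              non_sense = sum(effects$effect == "STOP_GAINED"),
              silent = sum(effects$effect %in%
                             c("SYNONYMOUS_CODING", "SYNONYMOUS_STOP")))

  rows <- lapply(panel$samples, function(s) {
    g <- panel$geno[, s]
    nonref <- !is.na(g) & g >= 1L
    r <- table(reg[nonref])
    e <- table(eff[nonref])
    data.frame(sample = s, t(as.matrix(c(r, e))),
               total = sum(nonref), check.names = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL
  list(genome = genome, per_sample = per_sample)
}
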