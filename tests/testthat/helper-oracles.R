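# Independent whole-CDS re-translation oracle: mutate the chromosome,
# re-extract the CDS from its GFF intervals, translate reference and mutant
# proteins with Biostrings and classify from the diff. Shares no code with
# the package's per-codon annotator.
oracle_snp_class <- function(reference, genes, gene_id, pos, ref, alt) {
  g <- genes$genes[genes$genes$gene_id == gene_id, ]
  seg <- genes$cds[genes$cds$gene_id == gene_id, ]
  seg <- seg[order(seg$start), ]
  chrom_seq <- strsplit(as.character(reference[[g$chrom]]), "")[[1]]
  stopifnot(chrom_seq[pos] == ref)
  alt_seq <- chrom_seq
  alt_seq[pos] <- alt
  extract <- function(ch) {
    s <- paste(unlist(Map(function(a, b) ch[a:b], seg$start, seg$end)),
               collapse = "")
    if (g$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  cds_ref <- extract(chrom_seq)
  cds_alt <- extract(alt_seq)
  i <- which(strsplit(cds_ref, "")[[1]] != strsplit(cds_alt, "")[[1]])
  ci <- (i - 1) %/% 3 + 1
  n_cod <- nchar(cds_ref) / 3
  codon <- function(s) substr(s, (ci - 1) * 3 + 1, ci * 3)
  p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_ref)))
  p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(cds_alt)))
  if (ci == 1) {
    if (codon(cds_alt) %in% c("CTG", "TTG", "GTG"))
      return("NON_SYNONYMOUS_START")
    return("START_LOST")
  }
  if (p_ref == p_alt)
    return(if (ci == n_cod && substr(p_ref, ci, ci) == "*")
             "SYNONYMOUS_STOP" else "SYNONYMOUS_CODING")
  aa_r <- substr(p_ref, ci, ci)
  aa_a <- substr(p_alt, ci, ci)
  if (aa_r != "*" && aa_a == "*") return("STOP_GAINED")
  if (aa_r == "*" && aa_a != "*") return("STOP_LOST")
  "NON_SYNONYMOUS_CODING"
}

# Draw n random coding SNPs over the given genes; returns a classified site
# table plus the gene each site belongs to.
random_coding_snps <- function(reference, genes, n) {
  cds <- genes$cds
  widths <- cds$end - cds$start + 1L
  rows <- sample.int(nrow(cds), n, replace = TRUE, prob = widths)
  pos <- cds$start[rows] +
    vapply(widths[rows], function(w) sample.int(w, 1) - 1L, integer(1))
  chrom <- cds$chrom[rows]
  ref <- vapply(seq_len(n), function(i)
    panelvar:::chrom_bases(reference, chrom[i], pos[i]), character(1))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  list(sites = classify_variants(
         data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt)),
       gene_id = cds$gene_id[rows])
}
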