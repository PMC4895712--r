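test_that("single codon substitutions classify by the genetic code", {
  cc <- panelvar:::classify_codon_change
  expect_equal(cc("GAA", "GAG", 5, 100), "SYNONYMOUS_CODING")  # Glu = Glu
  expect_equal(cc("TGG", "TGA", 5, 100), "STOP_GAINED")        # Trp -> stop
  expect_equal(cc("ATG", "ATA", 1, 100), "START_LOST")
  expect_equal(cc("ATG", "CTG", 1, 100), "NON_SYNONYMOUS_START")
  expect_equal(cc("TAA", "TAG", 100, 100), "SYNONYMOUS_STOP")
  expect_equal(cc("TGA", "TGG", 100, 100), "STOP_LOST")
  expect_equal(cc("GCA", "CCA", 5, 100), "NON_SYNONYMOUS_CODING")
})

test_that("variants locate to exon, intron and intergenic regions", {
  fx <- small_fixture()
  genes <- fx$p$genes
  two_exon <- names(which(table(genes$cds$gene_id) == 2))[1]
  expect_false(is.na(two_exon))
  seg <- genes$cds[genes$cds$gene_id == two_exon, ]
  seg <- seg[order(seg$start), ]
  g <- genes$genes[genes$genes$gene_id == two_exon, ]
  sites <- data.frame(
    chrom = g$chrom,
    pos = c(seg$start[1] + 5L,             # inside first exon
            seg$end[1] + 3L,               # between the exons
            g$start - 500L))               # upstream of the gene
  loc <- locate_variants(sites, genes)
  expect_equal(loc$region, c("EXON", "INTRON", "INTERGENIC"))
  expect_equal(loc$gene_id, c(two_exon, two_exon, NA))
})

test_that("coding indels split into frameshift and codon events", {
  fx <- small_fixture()
  genes <- fx$p$genes
  ref <- fx$p$reference
  seg <- genes$cds[which.max(genes$cds$end - genes$cds$start), ]
  p0 <- seg$start + 15L
  anchor <- panelvar:::chrom_bases(ref, seg$chrom, p0)
  sites <- classify_variants(data.frame(
    chrom = seg$chrom, pos = p0 + c(0L, 40L, 80L),
    ref = c(panelvar:::chrom_substr(ref, seg$chrom, p0, p0 + 2L),
            panelvar:::chrom_bases(ref, seg$chrom, p0 + 40L),
            panelvar:::chrom_substr(ref, seg$chrom, p0 + 80L, p0 + 86L)),
    alt = c(anchor,
            paste0(panelvar:::chrom_bases(ref, seg$chrom, p0 + 40L), "ACG"),
            panelvar:::chrom_bases(ref, seg$chrom, p0 + 80L))))
  pmx <- list(sites = sites)
  ann <- annotate_panel(pmx, genes, ref)
  expect_equal(ann$effect, c("FRAME_SHIFT",      # 2 bp deletion
                             "CODON_INSERTION",  # 3 bp insertion
                             "CODON_DELETION"))  # 6 bp deletion
})

test_that("a reference-allele mismatch is a hard error", {
  fx <- small_fixture()
  genes <- fx$p$genes
  seg <- genes$cds[1, ]
  pos <- seg$start + 9L
  truth_base <- panelvar:::chrom_bases(fx$p$reference, seg$chrom, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  sites <- classify_variants(data.frame(chrom = seg$chrom, pos = pos,
                                        ref = wrong, alt = truth_base))
  expect_error(annotate_panel(list(sites = sites), genes, fx$p$reference),
               "mismatch")
})

test_that("SNP classification matches the whole-CDS re-translation oracle on both strands", {
  fx <- small_fixture()
  genes <- fx$p$genes
  ref <- fx$p$reference
  set.seed(55)
  n_per_gene <- 25
  for (gid in genes$genes$gene_id) {
    seg <- genes$cds[genes$cds$gene_id == gid, ]
    pool <- unlist(Map(seq.int, seg$start, seg$end))
    pos <- sample(pool, n_per_gene)
    chrom <- genes$genes$chrom[genes$genes$gene_id == gid]
    for (p in pos) {
      r <- panelvar:::chrom_bases(ref, chrom, p)
      a <- sample(setdiff(c("A", "C", "G", "T"), r), 1)
      sites <- classify_variants(data.frame(chrom = chrom, pos = p,
                                            ref = r, alt = a))
      got <- annotate_panel(list(sites = sites), genes, ref)$effect
      expect_equal(got, oracle_snp_class(ref, genes, gid, p, r, a),
                   info = sprintf("%s %s:%d %s>%s", gid, chrom, p, r, a))
    }
  }
})

test_that("annotation is invariant under strand mirroring", {
  fx <- small_fixture()
  genes <- fx$p$genes
  ref <- fx$p$reference
  chrom <- genes$genes$chrom[1]
  L <- Biostrings::width(ref)[match(chrom, names(ref))]

  mirror_ref <- ref
  mirror_ref[[chrom]] <- Biostrings::reverseComplement(ref[[chrom]])
  mir <- function(df) {
    df2 <- df
    df2$start <- L - df$end + 1L
    df2$end <- L - df$start + 1L
    df2
  }
  on_chrom <- genes$genes$chrom == chrom
  g2 <- mir(genes$genes[on_chrom, ])
  g2$strand <- ifelse(g2$strand == "+", "-", "+")
  mirror_genes <- gene_models(g2,
                              mir(genes$exons[genes$exons$chrom == chrom, ]),
                              mir(genes$cds[genes$cds$chrom == chrom, ]))

  set.seed(77)
  seg <- genes$cds[genes$cds$chrom == chrom, ]
  pool <- unlist(Map(seq.int, seg$start, seg$end))
  for (p in sample(pool, 40)) {
    r <- panelvar:::chrom_bases(ref, chrom, p)
    a <- sample(setdiff(c("A", "C", "G", "T"), r), 1)
    fwd <- annotate_panel(list(sites = classify_variants(
      data.frame(chrom = chrom, pos = p, ref = r, alt = a))),
      genes, ref)$effect
    pm <- L - p + 1L
    rm_ <- panelvar:::comp_base(r)
    am <- panelvar:::comp_base(a)
    rev <- annotate_panel(list(sites = classify_variants(
      data.frame(chrom = chrom, pos = pm, ref = rm_, alt = am))),
      mirror_genes, mirror_ref)$effect
    expect_equal(rev, fwd, info = sprintf("%s:%d %s>%s", chrom, p, r, a))
  }
})

test_that("every coding SNP gets exactly one effect class and summaries reconcile", {
  fx <- small_fixture()
  pm <- fx$res$panel_matrix
  eff <- fx$res$effects
  expect_equal(nrow(eff), nrow(pm$sites))
  coding_snp <- eff$region == "EXON" & pm$sites$kind == "SNP"
  expect_true(all(eff$effect[coding_snp] != "NONE"))
  expect_true(all(eff$effect[eff$region != "EXON"] == "NONE"))

  sm <- summarize_effects(pm, eff)
  expect_equal(unname(sm$genome["mis_sense"] + sm$genome["non_sense"] +
                        sm$genome["silent"] +
                        sum(eff$effect %in% c("START_LOST", "STOP_LOST",
                                              "FRAME_SHIFT",
                                              "CODON_INSERTION",
                                              "CODON_DELETION"))),
               sum(eff$region == "EXON"))

  # planted effect classes are recovered exactly
  fe <- evaluate_forced_effects(pm, eff, fx$p$truth)
  expect_equal(fe$n_correct, fe$n_truth)
})
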