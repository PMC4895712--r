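test_that("reference generation honours gene-model contracts", {
  cfg <- small_config(seed = 5)
  ref <- generate_reference(cfg)
  expect_equal(length(ref$reference), 2L)
  expect_equal(unname(Biostrings::width(ref$reference)),
               rep(cfg$chromosome_length, 2))
  expect_true(all(strsplit(as.character(ref$reference[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_equal(nrow(ref$genes$genes), 8L)
  expect_setequal(unique(ref$genes$genes$strand), c("+", "-"))

  # per gene: CDS length divisible by 3, ATG start, stop end, no internal
  # stop; checked with an independent whole-CDS translation
  for (gid in ref$genes$genes$gene_id) {
    coding <- panelvar:::cds_coding_seq(ref$genes, gid, ref$reference)
    expect_equal(nchar(coding) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(coding)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }

  # genes do not overlap within a chromosome
  for (chrom in unique(ref$genes$genes$chrom)) {
    g <- ref$genes$genes[ref$genes$genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("an empty gene set and a deterministic sequence are supported", {
  cfg <- small_config(seed = 6, n_genes = 0, n_gene_deletions = 0,
                      n_gene_duplications = 0,
                      forced_effects = integer(0))
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$genes$genes), 0L)

  r1 <- generate_reference(small_config(seed = 9))
  r2 <- generate_reference(small_config(seed = 9))
  expect_identical(as.character(r1$reference), as.character(r2$reference))
  expect_identical(r1$genes$cds, r2$genes$cds)
})

test_that("variant planting keeps its books", {
  fx <- small_fixture()
  tv <- fx$p$truth$variants

  # 3 samples x 5 line-specific variants
  ls <- tv[tv$line_specific, ]
  expect_equal(nrow(ls), 15L)
  expect_equal(length(unique(paste(ls$chrom, ls$pos))), 15L)

  # no two planted variants of one sample share a position
  for (s in unique(tv$sample)) {
    sub <- tv[tv$sample == s, ]
    expect_false(any(duplicated(paste(sub$chrom, sub$pos))))
  }

  # total truth calls equal the union of per-sample call tables
  expect_equal(nrow(tv), sum(vapply(fx$p$calls, nrow, integer(1))))

  # shared (non-line-specific, unforced) sites have at least two carriers
  shared <- tv[!tv$line_specific, ]
  carriers <- table(paste(shared$chrom, shared$pos))
  expect_true(all(carriers >= 2))

  # heterozygous fraction is binomially consistent with the configured 0.3
  n <- nrow(tv)
  phat <- mean(tv$zygosity == "het")
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("rate zero and infeasible spacing behave as specified", {
  cfg <- small_config(seed = 7, snp_rate = 0, indel_rate = 0,
                      n_line_specific = 0, forced_effects = integer(0))
  ref <- generate_reference(cfg)
  pv <- simulate_panel_variants(ref$reference, ref$genes, cfg)
  expect_equal(nrow(pv$truth$variants), 0L)
  expect_true(all(vapply(pv$calls, nrow, integer(1)) == 0L))

  expect_error(panelvar:::spaced_positions(1000, 1, 5000, 65),
               "flank spacing")
})

test_that("depth profiles realize deletions, duplications and a clean control", {
  fx <- small_fixture()
  p <- fx$p
  ev <- p$truth$gene_events
  for (i in seq_len(nrow(ev))) {
    g <- p$genes$genes[p$genes$genes$gene_id == ev$gene_id[i], ]
    st <- gene_coverage_stats(p$depth[[ev$sample[i]]], g)
    if (ev$event[i] == "deletion") {
      expect_lt(st$breadth, 0.10)
      expect_gt(st$breadth, 0)     # residual mis-mapping analog retained
    } else {
      expect_gt(st$depth_ratio, 1.9)
    }
  }
  expect_false(control_has_events <- any(ev$sample == "control"))
  ctrl_calls <- call_gene_events(p$depth$control, p$genes, "control")
  expect_true(all(ctrl_calls$pav == "PRESENT"))
  expect_true(all(ctrl_calls$duplication == "NORMAL"))
})

test_that("discordant pairs realize the planted event geometries", {
  fx <- small_fixture()
  p <- fx$p
  sv <- p$truth$sv_events
  for (s in unique(sv$sample)) {
    pr <- p$pairs[[s]]
    # CTX pairs have differing mate chromosomes
    ctx <- pr[grepl("_CTX_", pr$name), ]
    expect_true(all(ctx$chrom1 != ctx$chrom2))
    # INV pairs share an orientation within each event
    inv <- pr[grepl("_INV_", pr$name), ]
    ev_id <- sub("_rp\\d+$", "", inv$name)
    for (e in unique(ev_id)) {
      sub <- inv[ev_id == e, ]
      expect_equal(sub$strand1, sub$strand2)
      expect_equal(length(unique(sub$strand1)), 1L)
    }
    # ITX pairs: same chromosome, opposite orientation, long separation
    itx <- pr[grepl("_ITX_", pr$name), ]
    expect_true(all(itx$chrom1 == itx$chrom2))
    expect_true(all(itx$strand1 != itx$strand2))
    expect_true(all(itx$start2 - itx$end1 >
                      p$config$insert_size_mean + 3 * p$config$insert_size_sd))
  }
  expect_equal(nrow(p$pairs$control), 0L)

  # no planted events gives empty tables
  cfg0 <- small_config(seed = 12, n_sv_per_type = 0)
  ref0 <- generate_reference(cfg0)
  pv0 <- simulate_panel_variants(ref0$reference, ref0$genes, cfg0)
  pr0 <- simulate_discordant_pairs(ref0$reference, pv0$truth, cfg0)
  expect_true(all(vapply(pr0, nrow, integer(1)) == 0L))

  # breakpoints closer than a read length are rejected
  bad <- truth_set(
    data.frame(sample = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               zygosity = character(0), line_specific = logical(0),
               effect = character(0)),
    data.frame(sample = character(0), gene_id = character(0),
               event = character(0)),
    data.frame(sample = "S01", type = "INV", chromA = "Ca1", posA = 5000L,
               chromB = "Ca1", posB = 5050L))
  expect_error(simulate_discordant_pairs(fx$p$reference, bad, fx$p$config),
               "read_length")
})
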