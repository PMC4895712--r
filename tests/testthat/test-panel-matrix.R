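test_that("panel merging takes the union of sites", {
  a <- make_records("Ca1", c(10, 20, 30), "A", "T", "hom_alt", sample = "A")
  b <- make_records("Ca1", c(40, 50, 60), "A", "T", "hom_alt", sample = "B")
  pm <- build_panel(list(A = a, B = b))
  expect_equal(nrow(pm$sites), 6L)

  shared <- build_panel(list(A = a, B = a))
  expect_equal(nrow(shared$sites), 3L)
  expect_true(all(shared$geno == 2L))

  # same position, contradictory reference context
  c1 <- make_records("Ca1", 10, "A", "T", "hom_alt", sample = "A")
  c2 <- make_records("Ca1", 10, "G", "T", "hom_alt", sample = "B")
  expect_error(build_panel(list(A = c1, B = c2)), "conflicting reference")
})

test_that("absence of a call becomes hom-ref only where depth supports it", {
  a <- make_records("Ca1", c(100, 200), "A", "T", "hom_alt", sample = "A")
  b <- make_records("Ca1", 300, "A", "T", "het", sample = "B")
  depth <- list(
    A = flat_profile(c(Ca1 = 1000L), 10),
    B = list(Ca1 = c(S4Vectors::Rle(10L, 150), S4Vectors::Rle(0L, 850))))
  pm <- build_panel(list(A = a, B = b), depth = depth)
  i100 <- which(pm$sites$pos == 100)
  i200 <- which(pm$sites$pos == 200)
  i300 <- which(pm$sites$pos == 300)
  expect_equal(unname(pm$geno[i100, "B"]), 0L)          # covered: confident hom-ref
  expect_true(is.na(pm$geno[i200, "B"]))        # uncovered: missing
  expect_equal(unname(pm$geno[i300, "A"]), 0L)
  # without depth, absence defaults to hom-ref
  pm2 <- build_panel(list(A = a, B = b))
  expect_equal(unname(pm2$geno[i200, "B"]), 0L)
})

test_that("zygosity counts and heterozygosity rate follow het/(het+hom)", {
  rec <- make_records("Ca1", c(10, 20, 30, 40), "A", "T",
                      c("het", "hom_alt", "hom_alt", "hom_alt"), sample = "A")
  pm <- build_panel(list(A = rec))
  z <- zygosity_counts(pm, "A")
  expect_equal(z$n_het, 1L)
  expect_equal(z$n_hom, 3L)
  expect_equal(z$heterozygosity_rate, 0.25)

  allhom <- build_panel(list(A = make_records("Ca1", c(10, 20), "A", "T",
                                              "hom_alt", sample = "A")))
  expect_equal(zygosity_counts(allhom, "A")$heterozygosity_rate, 0)
  expect_error(zygosity_counts(pm, "nope"), "unknown sample")
})

test_that("pairwise SNP counts are genotype disagreements, symmetric, and match a per-site oracle", {
  a <- make_records("Ca1", 1:100, "A", "T", "hom_alt", sample = "A")
  b <- make_records("Ca1", 1:100, "A", "T", "hom_alt", sample = "B")
  pm <- build_panel(list(A = a, B = b))
  expect_equal(pairwise_snp_count(pm, "A", "B"), 0L)
  expect_error(pairwise_snp_count(pm, "A", "A"), "differ")

  pm2 <- build_panel(list(A = a, B = b[0, ]))  # B hom-ref everywhere
  expect_equal(pairwise_snp_count(pm2, "A", "B"), 100L)

  set.seed(31)
  gts <- c("het", "hom_alt")
  r1 <- make_records("Ca1", sort(sample.int(10000, 400)), "A", "T",
                     sample(gts, 400, TRUE), sample = "A")
  r2 <- make_records("Ca1", sort(sample.int(10000, 400)), "A", "T",
                     sample(gts, 400, TRUE), sample = "B")
  pm3 <- build_panel(list(A = r1, B = r2))
  # exhaustive per-site comparison
  oracle <- sum(vapply(seq_len(nrow(pm3$sites)), function(i) {
    ga <- pm3$geno[i, "A"]; gb <- pm3$geno[i, "B"]
    !is.na(ga) && !is.na(gb) && ga != gb
  }, logical(1)))
  expect_equal(pairwise_snp_count(pm3, "A", "B"), oracle)
  expect_equal(pairwise_snp_count(pm3, "A", "B"),
               pairwise_snp_count(pm3, "B", "A"))
  m <- pairwise_snp_matrix(pm3)
  expect_equal(m["A", "B"], oracle)
  expect_equal(diag(m), c(A = 0L, B = 0L))
})

test_that("line-specific detection requires hom-ref in every other genotype", {
  mk <- function(s, pos) make_records("Ca1", pos, "A", "T", "hom_alt",
                                      sample = s)
  # alt in exactly 1 of 5 samples
  recs <- c(list(S1 = mk("S1", 100)),
            lapply(paste0("S", 2:5), function(s) mk(s, integer(0))))
  names(recs) <- paste0("S", 1:5)
  pm <- build_panel(recs)
  ls <- line_specific_variants(pm)
  expect_equal(nrow(ls$S1$snps), 1L)

  # alt in 2 samples: not line-specific
  recs2 <- recs; recs2$S2 <- mk("S2", 100)
  ls2 <- line_specific_variants(build_panel(recs2))
  expect_true(all(vapply(ls2, function(x) nrow(x$snps), integer(1)) == 0L))

  # one other sample missing at the site: disqualified
  depth <- c(lapply(paste0("S", 1:4), function(s) flat_profile(c(Ca1 = 1000L))),
             list(flat_profile(c(Ca1 = 1000L), depth = 0)))
  names(depth) <- paste0("S", 1:5)
  pm3 <- build_panel(recs, depth = depth)
  ls3 <- line_specific_variants(pm3)
  expect_equal(nrow(ls3$S1$snps), 0L)
})

test_that("indel ratio is insertions over deletions with an absent value at zero deletions", {
  mk_indels <- function(n_ins, n_del, sample) {
    pos <- seq(10, by = 100, length.out = n_ins + n_del)
    make_records("Ca1", pos,
                 c(rep("A", n_ins), rep("ACG", n_del)),
                 c(rep("AT", n_ins), rep("A", n_del)),
                 "hom_alt", sample = sample)
  }
  pm <- build_panel(list(A = mk_indels(50, 50, "A")))
  expect_equal(indel_ratio(pm, "A"), 1.0)
  pm2 <- build_panel(list(A = mk_indels(103, 100, "A")))
  expect_equal(indel_ratio(pm2, "A"), 1.03)
  pm3 <- build_panel(list(A = mk_indels(0, 10, "A")))
  expect_equal(indel_ratio(pm3, "A"), 0.0)
  pm4 <- build_panel(list(A = mk_indels(5, 0, "A")))
  expect_true(is.na(indel_ratio(pm4, "A")))
})

test_that("planted line-specific truth is recovered exactly on the simulated panel", {
  fx <- small_fixture()
  ev <- evaluate_line_specific(fx$res$panel_matrix, fx$p$truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})

test_that("merging conserves per-sample call counts and ignores sample order", {
  fx <- small_fixture()
  kept <- lapply(fx$res$filtered, `[[`, "kept")
  pm <- fx$res$panel_matrix
  ss <- sample_summary(pm)
  for (s in pm$samples) {
    k <- kept[[s]]
    expect_equal(ss$n_snps[ss$sample == s], sum(k$kind == "SNP"))
    expect_equal(ss$n_insertions[ss$sample == s] +
                   ss$n_deletions[ss$sample == s],
                 sum(k$kind %in% c("INSERTION", "DELETION")))
  }
  perm <- rev(names(kept))
  pm_perm <- build_panel(kept[perm], depth = fx$p$depth)
  ss_perm <- sample_summary(pm_perm)
  expect_equal(ss_perm[match(ss$sample, ss_perm$sample), ], ss,
               ignore_attr = TRUE)
  expect_equal(pairwise_snp_matrix(pm_perm)[pm$samples, pm$samples],
               pairwise_snp_matrix(pm))
})
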