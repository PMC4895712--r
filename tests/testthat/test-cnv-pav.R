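test_that("presence/absence thresholds are <10% absent and >50% present", {
  expect_equal(call_pav(0.05), "ABSENT")
  expect_equal(call_pav(0.30), "AMBIGUOUS")
  expect_equal(call_pav(0.60), "PRESENT")
  expect_equal(call_pav(0.10), "AMBIGUOUS")   # boundary: 0.10 is not < 0.10
  expect_equal(call_pav(0.50), "AMBIGUOUS")   # boundary: 0.50 is not > 0.50
})

test_that("duplication calls use the normalized depth ratio", {
  expect_equal(call_duplication(2.0), "DUPLICATED")
  expect_equal(call_duplication(1.0), "NORMAL")
  expect_equal(call_duplication(1.75), "DUPLICATED")
  expect_error(call_duplication(-1), "negative")
})

test_that("gene coverage statistics come from breadth and normalized mean depth", {
  prof <- flat_profile(c(Ca1 = 10000L), 10)
  gene <- data.frame(chrom = "Ca1", start = 1001L, end = 3000L)
  st <- gene_coverage_stats(prof, gene)
  expect_equal(st$breadth, 1.0)
  expect_equal(st$depth_ratio, 1.0)

  prof0 <- flat_profile(c(Ca1 = 10000L), 0)
  st0 <- gene_coverage_stats(prof0, gene, median_depth = 10)
  expect_equal(st0$breadth, 0.0)
  expect_equal(st0$depth_ratio, 0.0)

  short <- data.frame(chrom = "Ca1", start = 1L, end = 999L)
  expect_error(gene_coverage_stats(prof, short), "1,000 bp")
})

test_that("genes shorter than 1 kb are excluded from panel calling", {
  genes <- gene_models(
    data.frame(gene_id = c("gA", "gB"), chrom = "Ca1", strand = "+",
               start = c(1001L, 5001L), end = c(1999L, 6500L)),
    data.frame(gene_id = c("gA", "gB"), chrom = "Ca1",
               start = c(1001L, 5001L), end = c(1999L, 6500L), rank = 1L),
    data.frame(gene_id = c("gA", "gB"), chrom = "Ca1",
               start = c(1001L, 5001L), end = c(1999L, 6500L), rank = 1L,
               phase = 0L))
  calls <- call_gene_events(flat_profile(c(Ca1 = 10000L)), genes, "S")
  expect_equal(calls$gene_id, "gB")            # gA is 999 bp
  expect_equal(attr(calls, "excluded")$gene_id, "gA")
})

test_that("control exclusion drops shared events, keeps the rest, and is idempotent", {
  ev <- data.frame(sample = c("S1", "S1", "S2"),
                   gene_id = c("g1", "g2", "g3"),
                   event = c("deletion", "duplication", "deletion"))
  ctrl <- data.frame(sample = "control", gene_id = "g1", event = "deletion")
  out <- exclude_control(ev, ctrl)
  expect_equal(out$gene_id, c("g2", "g3"))
  expect_equal(exclude_control(out, ctrl), out)
  expect_equal(exclude_control(ev, ev[0, ]), ev)
  expect_error(exclude_control(ev, NULL), "control")
})

test_that("panel event sets separate non-redundant, line-specific and per-gene counts", {
  ev <- data.frame(
    sample = c("S1", "S2", "S3", "S1", "S2"),
    gene_id = c("g1", "g1", "g1", "g2", "g3"),
    event = c("duplication", "duplication", "duplication",
              "duplication", "deletion"))
  sets <- gene_event_sets(ev)
  expect_setequal(sets$non_redundant_duplicated, c("g1", "g2"))
  expect_equal(sets$non_redundant_absent, "g3")
  pg <- sets$per_gene_sample_counts
  expect_equal(pg$n_samples[pg$gene_id == "g1"], 3L)
  expect_setequal(sets$line_specific$gene_id, c("g2", "g3"))

  empty <- gene_event_sets(ev[0, ])
  expect_length(empty$non_redundant_duplicated, 0L)
  expect_equal(nrow(empty$line_specific), 0L)
})

test_that("increasing breadth never moves a call toward ABSENT", {
  grid <- seq(0, 1, by = 0.01)
  calls <- call_pav(grid)
  rank <- c(ABSENT = 1L, AMBIGUOUS = 2L, PRESENT = 3L)
  expect_true(all(diff(rank[calls]) >= 0L))
})

test_that("planted gene deletions and duplications are recovered exactly", {
  fx <- small_fixture()
  ev <- evaluate_gene_events(fx$res$gene_events, fx$p$truth)
  expect_equal(ev$deletion$precision, 1)
  expect_equal(ev$deletion$recall, 1)
  expect_equal(ev$duplication$precision, 1)
  expect_equal(ev$duplication$recall, 1)
})
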