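mk_pairs <- function(chrom1, start1, chrom2, start2,
                     strand1 = "+", strand2 = "-", mapq = 60, rl = 100,
                     prefix = "rp") {
  n <- max(length(start1), length(start2))
  data.frame(chrom1 = rep_len(chrom1, n),
             start1 = as.integer(rep_len(start1, n)),
             end1 = as.integer(rep_len(start1, n) + rl),
             chrom2 = rep_len(chrom2, n),
             start2 = as.integer(rep_len(start2, n)),
             end2 = as.integer(rep_len(start2, n) + rl),
             name = paste0(prefix, seq_len(n)),
             mapq = rep_len(mapq, n),
             strand1 = rep_len(strand1, n), strand2 = rep_len(strand2, n),
             sample = "S")
}

test_that("single-linkage clustering groups jittered pairs and separates distant events", {
  jit <- c(0, 30, 60, 90, 120)
  p1 <- mk_pairs("Ca1", 10000 + jit, "Ca2", 50000 + jit)
  cl <- cluster_pairs(p1, max_gap = 520)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 5L)

  p2 <- rbind(p1, mk_pairs("Ca1", 40000 + jit, "Ca2", 90000 + jit,
                           prefix = "q"))
  cl2 <- cluster_pairs(p2, max_gap = 520)
  expect_length(cl2, 2L)

  # low mapping quality is discarded before clustering
  p3 <- p1
  p3$mapq <- c(60, 60, 29, 60, 60)
  expect_equal(nrow(cluster_pairs(p3, max_gap = 520)[[1]]), 4L)
})

test_that("clustering matches an independent graph-components oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 120
    centers <- sample(seq(5000, 2e5, by = 15000), 8)
    p <- do.call(rbind, lapply(seq_along(centers), function(k) {
      m <- sample(2:6, 1)
      mk_pairs("Ca1", centers[k] + sample(0:400, m),
               "Ca2", centers[k] + 30000 + sample(0:400, m),
               prefix = paste0("c", k, "_"))
    }))
    max_gap <- 520
    cl <- cluster_pairs(p, max_gap)
    pc <- canonicalize_pairs(p)
    gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s1, s2) - pmin(e1, e2))
    adj <- outer(seq_len(nrow(pc)), seq_len(nrow(pc)), function(i, j) {
      pc$chrom1[i] == pc$chrom1[j] & pc$chrom2[i] == pc$chrom2[j] &
        gap(pc$start1[i], pc$end1[i], pc$start1[j], pc$end1[j]) <= max_gap &
        gap(pc$start2[i], pc$end2[i], pc$start2[j], pc$end2[j]) <= max_gap
    })
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    oracle_sets <- unname(lapply(split(pc$name, comp), sort))
    got_sets <- unname(lapply(cl, function(d) sort(d$name)))
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(oracle_sets, paste, collapse = ","))
  }
})

test_that("cluster geometry determines the variant type", {
  ctx <- mk_pairs("Ca1", c(1000, 1050), "Ca2", c(5000, 5050))
  expect_equal(classify_cluster(ctx, 400, 40), "CTX")

  inv <- mk_pairs("Ca1", c(1000, 1050), "Ca1", c(9000, 9050),
                  strand1 = "+", strand2 = "+")
  expect_equal(classify_cluster(inv, 400, 40), "INV")

  itx <- mk_pairs("Ca1", c(1000, 1050), "Ca1", c(21000, 21050))
  expect_equal(classify_cluster(itx, 400, 40), "ITX")  # 50x the insert size

  concordant <- mk_pairs("Ca1", c(1000, 1050), "Ca1", c(1200, 1250))
  expect_true(is.na(classify_cluster(concordant, 400, 40)))
  expect_error(classify_cluster(ctx[1, ], 400, 40), "two pairs")
})

test_that("scores are capped linear in support and filtered at 99", {
  five <- mk_pairs("Ca1", 1000 + 0:4 * 10, "Ca2", 5000 + 0:4 * 10)
  expect_equal(score_cluster(five), 99L)
  expect_equal(score_cluster(five[1:2, ]), 40L)

  calls <- call_svs(rbind(five,
                          mk_pairs("Ca1", 40000 + 0:3 * 10,
                                   "Ca2", 90000 + 0:3 * 10, prefix = "q")),
                    insert_size_mean = 400, insert_size_sd = 40)
  expect_equal(sort(calls$score), c(80L, 99L))   # 4 and 5 supporting pairs
  kept <- filter_and_exclude(calls, min_score = 99)
  expect_equal(kept$n_supporting, 5L)            # the 80 (.e. <99) call drops

  # a single supporting pair never becomes a call
  single <- mk_pairs("Ca1", 70000, "Ca2", 110000)
  expect_equal(nrow(call_svs(rbind(five, single), 400, 40)), 1L)

  # control overlap removes an otherwise perfect call
  ctrl <- call_svs(five, 400, 40)
  expect_equal(nrow(filter_and_exclude(calls, ctrl, min_score = 99,
                                       max_gap = 520)), 0L)
})

test_that("breakpoints refine to the innermost supporting edges", {
  cl <- data.frame(chrom1 = "Ca1", start1 = c(900, 905, 903),
                   end1 = c(1000, 1005, 1003),
                   chrom2 = "Ca1", start2 = c(9000, 9010, 9004),
                   end2 = c(9100, 9110, 9104),
                   name = paste0("r", 1:3), mapq = 60,
                   strand1 = "+", strand2 = "-")
  bp <- refine_breakpoints(cl)
  expect_equal(bp$posA, 1006L)   # max 0-based-exclusive end 1005, plus one
  expect_equal(bp$posB, 9001L)   # min 0-based start 9000, to 1-based
  expect_true(bp$refined)
  # the refined interval sits inside the raw cluster extent
  expect_gte(bp$posA, min(cl$start1) + 1L)
  expect_lte(bp$posB, max(cl$end2))

  # refined breakpoints land within one insert-size SD of planted truth
  fx <- small_fixture()
  ev <- evaluate_sv(fx$res$sv_calls, fx$p$truth)
  expect_true(all(ev$breakpoint_errors$errA <= fx$p$config$insert_size_sd))
  expect_true(all(ev$breakpoint_errors$errB <= fx$p$config$insert_size_sd))
})

test_that("planted structural events recover with a diagonal confusion matrix", {
  fx <- small_fixture()
  ev <- evaluate_sv(fx$res$sv_calls, fx$p$truth)
  n <- nrow(fx$p$truth$sv_events)
  expect_equal(sum(diag(ev$confusion)), n)
  expect_equal(sum(ev$confusion) - sum(diag(ev$confusion)), 0L)
  expect_equal(ev$n_unmatched_calls, 0L)
  expect_equal(ev$n_missed_truth, 0L)
  # CTX calls never share a chromosome
  ctx <- fx$res$sv_calls[fx$res$sv_calls$sv_type == "CTX", ]
  expect_true(all(ctx$chromA != ctx$chromB))
})

test_that("the type-by-chromosome summary reconciles with its totals", {
  calls <- data.frame(sv_type = c("CTX", "CTX", "INV"),
                      chromA = c("Ca1", "Ca1", "Ca6"),
                      chromB = c("Ca2", "Ca3", "Ca6"),
                      posA = 1L, posB = 2L, size = c(300L, 400L, 5000L),
                      score = 99L, n_supporting = 5L, supporting_ids = "x",
                      refined = TRUE, sample = "S")
  sm <- summarize_sv(calls, paste0("Ca", 1:8))
  expect_equal(sm$matrix["CTX", "Ca1"], 2L)
  expect_equal(sm$matrix["INV", "Ca6"], 1L)
  expect_equal(sm$matrix["Total", "Total"], 3L)
  expect_equal(sm$size_ranges$min_size[sm$size_ranges$sv_type == "CTX"], 300L)

  empty <- summarize_sv(calls[0, ], paste0("Ca", 1:8))
  expect_true(all(empty$matrix == 0L))
})
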