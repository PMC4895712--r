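#' Structural-variant typing from discordant read pairs
#'
#' Discordant pairs with mapping quality of at least 30 are clustered by
#' single linkage: two pairs join when both mate spans lie within `max_gap`
#' (insert-size mean + 3 SD by default) of each other's corresponding spans.
#' A cluster of at least two pairs is typed by its mate geometry:
#'
#' * CTX (inter-chromosomal translocation): mates on different chromosomes;
#' * INV (inversion): same chromosome and identically oriented mates
#'   (`+/+` or `-/-`) in the majority of pairs;
#' * ITX (intra-chromosomal translocation): same chromosome,
#'   opposite-orientation mates whose separation exceeds the concordant
#'   insert-size model (or whose mate order is reversed).
#'
#' Clusters are scored min(99, 20 x supporting pairs) — a transparent capped
#' score sharing the 0-99 range and the confidence-saturation semantics of
#' the conventional discordant-pair score — filtered at score 99, purged of
#' calls whose breakpoint neighbourhoods overlap any control-supported
#' cluster, and refined to exact breakpoints from the innermost edges of the
#' supporting mate spans.
#'
#' @name sv_misc
NULL

#' Canonicalize pair orientation
#'
#' Ensures mate 1 sorts before mate 2 by (chromosome, start); swaps mates
#' (with their strands) where needed so clustering and refinement see a
#' stable geometry.
#' @param pairs Pair data.frame (BEDPE-like columns).
#' @return The pair data.frame with mates ordered.
#' @export
canonicalize_pairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom2 == pairs$chrom1 & pairs$start2 < pairs$start1)
  if (any(swap)) {
    p <- pairs[swap, ]
    pairs[swap, c("chrom1", "start1", "end1", "strand1")] <-
      p[, c("chrom2", "start2", "end2", "strand2")]
    pairs[swap, c("chrom2", "start2", "end2", "strand2")] <-
      p[, c("chrom1", "start1", "end1", "strand1")]
  }
  pairs
}

span_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s1, s2) - pmin(e1, e2))

#' Cluster discordant pairs by single linkage
#'
#' @param pairs One sample's pair data.frame.
#' @param max_gap Linkage distance in bases between corresponding mate
#'   spans.
#' @param min_mapq Minimum mapping quality retained.
#' @return List of pair data.frames (one per cluster), ordered by their
#'   leftmost coordinates.
#' @export
cluster_pairs <- function(pairs, max_gap, min_mapq = 30) {
  pairs <- pairs[pairs$mapq >= min_mapq, , drop = FALSE]
  pairs <- canonicalize_pairs(pairs)
  n <- nrow(pairs)
  if (!n) return(list())
  pairs <- pairs[order(pairs$chrom1, pairs$start1, pairs$chrom2,
                       pairs$start2, pairs$name), , drop = FALSE]

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (pairs$chrom1[i] != pairs$chrom1[j] ||
          pairs$chrom2[i] != pairs$chrom2[j]) next
      g1 <- span_gap(pairs$start1[i], pairs$end1[i],
                     pairs$start1[j], pairs$end1[j])
      g2 <- span_gap(pairs$start2[i], pairs$end2[i],
                     pairs$start2[j], pairs$end2[j])
      if (g1 <= max_gap && g2 <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  cl <- split(seq_len(n), comp)
  clusters <- lapply(cl, function(ii) pairs[ii, , drop = FALSE])
  ord <- order(vapply(clusters, function(d) d$chrom1[1], character(1)),
               vapply(clusters, function(d) min(d$start1), integer(1)),
               vapply(clusters, function(d) d$chrom2[1], character(1)),
               vapply(clusters, function(d) min(d$start2), integer(1)))
  unname(clusters[ord])
}

#' Classify a cluster's structural-variant type
#'
#' @param cluster Pair data.frame of one cluster (>= 2 pairs).
#' @param insert_size_mean,insert_size_sd Concordant insert-size model.
#' @return `"CTX"`, `"ITX"`, `"INV"`, or `NA_character_` when the geometry
#'   matches none (such clusters are dropped with a reason).
#' @export
classify_cluster <- function(cluster, insert_size_mean, insert_size_sd) {
  if (nrow(cluster) < 2L)
    stop("classify_cluster: a cluster needs at least two pairs")
  if (cluster$chrom1[1] != cluster$chrom2[1]) return("CTX")
  same_orient <- cluster$strand1 == cluster$strand2
  if (mean(same_orient) > 0.5) return("INV")
  sep <- stats::median(cluster$start2 - cluster$end1)
  reversed <- stats::median(cluster$start2 - cluster$start1) < 0
  if (sep > insert_size_mean + 3 * insert_size_sd || reversed) return("ITX")
  NA_character_
}

#' Score a cluster
#'
#' min(99, 20 x number of supporting pairs): monotone in support and capped
#' at the 99 confidence ceiling, which a cluster reaches at five coherent
#' pairs.
#' @param cluster Pair data.frame of one cluster.
#' @return Integer score in 0-99.
#' @export
score_cluster <- function(cluster) {
  min(99L, 20L * nrow(cluster))
}

#' Type, score and refine all clusters of one sample
#'
#' @param pairs One sample's pair data.frame.
#' @param insert_size_mean,insert_size_sd Insert-size model.
#' @param min_mapq Minimum mapping quality retained.
#' @return data.frame of calls: `sv_type`, `chromA`, `posA`, `chromB`,
#'   `posB` (refined 1-based breakpoints), `size`, `score`, `n_supporting`,
#'   `supporting_ids`, `refined` flag, `sample`.
#' @export
call_svs <- function(pairs, insert_size_mean, insert_size_sd,
                     min_mapq = 30) {
  max_gap <- insert_size_mean + 3 * insert_size_sd
  clusters <- cluster_pairs(pairs, max_gap, min_mapq)
  clusters <- Filter(function(d) nrow(d) >= 2L, clusters)
  rows <- lapply(clusters, function(cl) {
    type <- classify_cluster(cl, insert_size_mean, insert_size_sd)
    if (is.na(type)) return(NULL)
    bp <- refine_breakpoints(cl)
    size <- if (type == "CTX") {
      (max(cl$end1) - min(cl$start1)) + (max(cl$end2) - min(cl$start2))
    } else {
      bp$posB - bp$posA
    }
    data.frame(sv_type = type, chromA = cl$chrom1[1], posA = bp$posA,
               chromB = cl$chrom2[1], posB = bp$posB, size = size,
               score = score_cluster(cl), n_supporting = nrow(cl),
               supporting_ids = paste(cl$name, collapse = ","),
               refined = bp$refined,
               sample = if ("sample" %in% names(cl)) cl$sample[1]
                        else NA_character_)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(sv_type = character(0), chromA = character(0),
                      posA = integer(0), chromB = character(0),
                      posB = integer(0), size = integer(0),
                      score = integer(0), n_supporting = integer(0),
                      supporting_ids = character(0), refined = logical(0),
                      sample = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Refine breakpoints from supporting mate spans
#'
#' Each breakpoint is placed at the innermost edge of its side's supporting
#' mate spans: reads oriented `+` point at the junction and end just before
#' it, so their breakpoint is the maximum span end plus one; reads oriented
#' `-` point away and start just after it, so their breakpoint is the
#' minimum span start converted to 1-based. The side's majority strand
#' picks the rule. Spans are 0-based half-open. With evidence on one side
#' only the raw coordinates are kept and the call is flagged unrefined.
#' @param cluster Pair data.frame of one cluster (canonical mate order).
#' @return List with `posA`, `posB` (1-based) and `refined` flag.
#' @export
refine_breakpoints <- function(cluster) {
  side_ok1 <- !is.na(cluster$end1) & !is.na(cluster$start1)
  side_ok2 <- !is.na(cluster$end2) & !is.na(cluster$start2)
  if (!any(side_ok1) || !any(side_ok2)) {
    return(list(posA = min(cluster$start1, na.rm = TRUE) + 1L,
                posB = max(cluster$end2, cluster$end1, na.rm = TRUE),
                refined = FALSE))
  }
  inner <- function(starts, ends, strands) {
    plus <- mean(strands == "+") >= 0.5
    if (plus) max(ends) + 1L else min(starts) + 1L
  }
  list(posA = inner(cluster$start1[side_ok1], cluster$end1[side_ok1],
                    cluster$strand1[side_ok1]),
       posB = inner(cluster$start2[side_ok2], cluster$end2[side_ok2],
                    cluster$strand2[side_ok2]),
       refined = TRUE)
}

#' Filter calls at the score cutoff and exclude control-supported loci
#'
#' @param calls SV call data.frame from [call_svs()].
#' @param control_calls SV clusters called from the control sample by the
#'   identical pipeline (score filter not applied to the control).
#' @param min_score Score cutoff (calls with `score >= min_score` kept; with
#'   the capped score, `>= 99` and `== 99` coincide).
#' @param max_gap Breakpoint-neighbourhood radius for control overlap.
#' @return Filtered call data.frame.
#' @export
filter_and_exclude <- function(calls, control_calls = NULL, min_score = 99,
                               max_gap = 0) {
  keep <- calls$score >= min_score
  calls <- calls[keep, , drop = FALSE]
  if (!is.null(control_calls) && nrow(control_calls) && nrow(calls)) {
    near <- function(chrom, pos, c_chrom, c_pos)
      chrom == c_chrom & abs(pos - c_pos) <= max_gap
    hit <- vapply(seq_len(nrow(calls)), function(i) {
      any(near(calls$chromA[i], calls$posA[i],
               control_calls$chromA, control_calls$posA) |
          near(calls$chromA[i], calls$posA[i],
               control_calls$chromB, control_calls$posB) |
          near(calls$chromB[i], calls$posB[i],
               control_calls$chromA, control_calls$posA) |
          near(calls$chromB[i], calls$posB[i],
               control_calls$chromB, control_calls$posB))
    }, logical(1))
    calls <- calls[!hit, , drop = FALSE]
  }
  calls
}

#' Summarize calls as a type-by-chromosome matrix with size ranges
#'
#' A CTX is counted on its A-side chromosome; same-chromosome events on
#' their single chromosome.
#' @param calls SV call data.frame (possibly across samples).
#' @param chroms Chromosome names (matrix columns).
#' @return List with `matrix` (types x chromosomes, with `Total` row and
#'   column) and `size_ranges` (data.frame `sv_type`, `min_size`,
#'   `max_size`).
#' @export
summarize_sv <- function(calls, chroms) {
  types <- c("CTX", "ITX", "INV")
  m <- matrix(0L, length(types), length(chroms),
              dimnames = list(types, chroms))
  for (i in seq_len(nrow(calls))) {
    m[calls$sv_type[i], calls$chromA[i]] <-
      m[calls$sv_type[i], calls$chromA[i]] + 1L
  }
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  sizes <- lapply(types, function(t) {
    s <- calls$size[calls$sv_type == t]
    data.frame(sv_type = t,
               min_size = if (length(s)) min(s) else NA_integer_,
               max_size = if (length(s)) max(s) else NA_integer_)
  })
  list(matrix = m, size_ranges = do.call(rbind, sizes))
}
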