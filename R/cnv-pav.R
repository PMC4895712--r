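#' Depth-based gene presence/absence and duplication calling
#'
#' Per-gene coverage statistics from a sample's depth profile: breadth (the
#' fraction of gene-span bases covered by at least `min_covered_depth`
#' reads) and the depth ratio (mean depth over the gene span divided by the
#' sample's genome-wide median depth). Only genes of at least 1,000 bp are
#' considered. Presence/absence is called on breadth — below 10% the gene is
#' ABSENT, above 50% PRESENT, between them AMBIGUOUS — and duplication on the
#' depth ratio at a default threshold of 1.75 (midpoint-plus-margin between
#' the one-copy and two-copy expectations). Events also called in the
#' reference control (reference reads mapped against the reference itself)
#' are excluded as false positives.
#'
#' @name cnv_pav
NULL

#' @rdname cnv_pav
#' @param profile One sample's depth profile (named list of per-chromosome
#'   [S4Vectors::Rle]).
#' @param gene One row of `genes$genes` (with `chrom`, `start`, `end`).
#' @param min_covered_depth Depth at which a base counts as covered.
#' @param median_depth Genome-wide median depth of the sample; computed from
#'   the profile when `NULL`.
#' @return `gene_coverage_stats()`: list with `breadth` and `depth_ratio`.
#' @export
gene_coverage_stats <- function(profile, gene, min_covered_depth = 1,
                                median_depth = NULL) {
  if (gene$end - gene$start + 1L < 1000L)
    stop("gene_coverage_stats: gene shorter than 1,000 bp is excluded ",
         "from CNV/PAV calling")
  if (is.null(median_depth)) median_depth <- genome_median_depth(profile)
  v <- S4Vectors::window(profile[[gene$chrom]], gene$start, gene$end)
  breadth <- sum(v >= min_covered_depth) / length(v)
  ratio <- if (median_depth == 0) 0 else mean(v) / median_depth
  list(breadth = breadth, depth_ratio = ratio)
}

#' @rdname cnv_pav
#' @param breadth Fraction in `[0, 1]` (or, under the alternative operand,
#'   a normalized depth fraction).
#' @return `call_pav()`: `"ABSENT"` (< 0.10), `"PRESENT"` (> 0.50) or
#'   `"AMBIGUOUS"`.
#' @export
call_pav <- function(breadth) {
  if (any(breadth < 0)) stop("call_pav: statistic must be non-negative")
  ifelse(breadth < 0.10, "ABSENT",
         ifelse(breadth > 0.50, "PRESENT", "AMBIGUOUS"))
}

#' @rdname cnv_pav
#' @param depth_ratio Mean gene depth over genome median depth.
#' @param threshold Duplication threshold on the ratio.
#' @return `call_duplication()`: `"DUPLICATED"` or `"NORMAL"`.
#' @export
call_duplication <- function(depth_ratio, threshold = 1.75) {
  if (any(depth_ratio < 0)) stop("call_duplication: negative depth ratio")
  ifelse(depth_ratio >= threshold, "DUPLICATED", "NORMAL")
}

#' Call gene events for one sample
#'
#' @param profile One sample's depth profile.
#' @param genes A [gene_models()] object.
#' @param sample Sample name recorded on the calls.
#' @param min_covered_depth Depth at which a base counts as covered.
#' @param dup_threshold Duplication threshold on the depth ratio.
#' @param pav_operand Statistic the presence/absence thresholds are applied
#'   to: `"breadth"` (default) or `"depth_ratio"`.
#' @return data.frame with one row per gene of >= 1,000 bp: `gene_id`,
#'   `sample`, `breadth`, `depth_ratio`, `pav`, `duplication`; genes below
#'   1,000 bp are listed in the `excluded` attribute with a reason.
#' @export
call_gene_events <- function(profile, genes, sample,
                             min_covered_depth = 1, dup_threshold = 1.75,
                             pav_operand = c("breadth", "depth_ratio")) {
  pav_operand <- match.arg(pav_operand)
  len <- gene_lengths(genes)
  keep <- names(len)[len >= 1000L]
  short <- setdiff(names(len), keep)
  excluded <- data.frame(gene_id = short,
                         reason = rep("gene shorter than 1,000 bp",
                                      length(short)))
  med <- genome_median_depth(profile)
  rows <- lapply(keep, function(gid) {
    g <- genes$genes[genes$genes$gene_id == gid, ]
    st <- gene_coverage_stats(profile, g, min_covered_depth, med)
    data.frame(gene_id = gid, sample = sample, breadth = st$breadth,
               depth_ratio = st$depth_ratio)
  })
  d <- do.call(rbind, rows)
  operand <- if (pav_operand == "breadth") d$breadth else d$depth_ratio
  d$pav <- call_pav(operand)
  d$duplication <- call_duplication(d$depth_ratio, dup_threshold)
  rownames(d) <- NULL
  attr(d, "excluded") <- excluded
  d
}

# Long-format (sample, gene_id, event) table from per-sample call tables.
gene_event_table <- function(calls) {
  del <- calls$pav == "ABSENT"
  dup <- calls$duplication == "DUPLICATED"
  ev <- rbind(
    data.frame(sample = calls$sample[del], gene_id = calls$gene_id[del],
               event = rep("deletion", sum(del))),
    data.frame(sample = calls$sample[dup], gene_id = calls$gene_id[dup],
               event = rep("duplication", sum(dup))))
  rownames(ev) <- NULL
  ev
}

#' Exclude events also called in the reference control
#'
#' @param events Event data.frame (`sample`, `gene_id`, `event`).
#' @param control_events Event data.frame of the control sample, produced by
#'   the identical pipeline.
#' @return `events` with every (gene, event) pair also present in the
#'   control removed. Idempotent.
#' @export
exclude_control <- function(events, control_events) {
  if (is.null(control_events))
    stop("exclude_control: control calls are required")
  if (!nrow(control_events)) return(events)
  bad <- paste(events$gene_id, events$event) %in%
    paste(control_events$gene_id, control_events$event)
  events[!bad, , drop = FALSE]
}

#' Panel-level gene event sets
#'
#' @param events Event data.frame (`sample`, `gene_id`, `event`) across all
#'   samples, after control exclusion.
#' @return List with `non_redundant_duplicated` and `non_redundant_absent`
#'   (gene-id vectors: the union of genes carrying the event in at least one
#'   sample), `line_specific` (data.frame of events seen in exactly one
#'   sample), and `per_gene_sample_counts` (data.frame `gene_id`, `event`,
#'   `n_samples`).
#' @export
gene_event_sets <- function(events) {
  if (!nrow(events)) {
    return(list(non_redundant_duplicated = character(0),
                non_redundant_absent = character(0),
                line_specific = events,
                per_gene_sample_counts = data.frame(
                  gene_id = character(0), event = character(0),
                  n_samples = integer(0))))
  }
  key <- paste(events$gene_id, events$event)
  cnt <- tapply(events$sample, key, function(s) length(unique(s)))
  first <- !duplicated(key)
  per_gene <- data.frame(gene_id = events$gene_id[first],
                         event = events$event[first],
                         n_samples = as.integer(cnt[key[first]]))
  ls_keys <- names(cnt)[cnt == 1L]
  list(
    non_redundant_duplicated =
      sort(unique(events$gene_id[events$event == "duplication"])),
    non_redundant_absent =
      sort(unique(events$gene_id[events$event == "deletion"])),
    line_specific = events[key %in% ls_keys, , drop = FALSE],
    per_gene_sample_counts = per_gene[order(per_gene$gene_id,
                                            per_gene$event), ])
}
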