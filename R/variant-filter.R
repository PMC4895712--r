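#' Variant retention filters and SNP/indel classification
#'
#' The retention rules applied to each genotype's raw calls before any panel
#' statistic is computed: a call is kept when its phred quality is strictly
#' greater than 30 and its supporting read depth is at least 5, and calls
#' with a same-chromosome neighbour closer than 5 bp (anchor-position
#' distance) are removed — both members of a too-close pair, since the rule
#' names no survivor. Retained records are classified as SNP (both alleles
#' one base), insertion or deletion (length difference 1-58 bp), or OTHER
#' (multi-nucleotide substitutions and events longer than 58 bp; these are
#' kept in an audit stream but excluded from all SNP/indel statistics).
#'
#' @name variant_filter
NULL

#' @rdname variant_filter
#' @param records Call data.frame with at least `chrom`, `pos`, `qual`, `dp`.
#' @param min_quality Minimum phred quality; strictly exceeded to keep.
#' @param min_depth Minimum read depth; met or exceeded to keep.
#' @return `filter_quality_depth()`: list with `kept` and `removed`
#'   data.frames (input order preserved).
#' @export
filter_quality_depth <- function(records, min_quality = 30, min_depth = 5) {
  if (min_quality < 0 || min_depth < 0)
    stop("filter_quality_depth: thresholds must be non-negative")
  keep <- records$qual > min_quality & records$dp >= min_depth
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' @rdname variant_filter
#' @param min_flank Minimum anchor-position distance to the nearest
#'   same-chromosome neighbour; records closer than this are removed.
#' @return `filter_flank_distance()`: list with `kept` and `removed`.
#' @export
filter_flank_distance <- function(records, min_flank = 5) {
  if (min_flank < 0)
    stop("filter_flank_distance: min_flank must be non-negative")
  n <- nrow(records)
  if (n == 0L) return(list(kept = records, removed = records))
  blocks <- rle(records$chrom)$values
  by_chrom <- split(records$pos,
                    factor(records$chrom, levels = unique(records$chrom)))
  if (anyDuplicated(blocks) ||
      any(vapply(by_chrom, is.unsorted, logical(1))))
    stop("filter_flank_distance: records must be sorted by (chrom, pos)")
  drop <- logical(n)
  for (chrom in unique(records$chrom)) {
    idx <- which(records$chrom == chrom)
    p <- records$pos[idx]
    if (length(p) > 1L) {
      gaps <- diff(p)
      close_left <- c(FALSE, gaps < min_flank)
      close_right <- c(gaps < min_flank, FALSE)
      drop[idx] <- close_left | close_right
    }
  }
  list(kept = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE])
}

#' @rdname variant_filter
#' @param max_indel Maximum indel length counted as an indel.
#' @return `classify_variants()`: the input with `kind` (`"SNP"`,
#'   `"INSERTION"`, `"DELETION"`, `"OTHER"`) and `len` columns added.
#' @export
classify_variants <- function(records, max_indel = 58) {
  nref <- nchar(records$ref)
  nalt <- nchar(records$alt)
  len <- abs(nalt - nref)
  kind <- rep("OTHER", nrow(records))
  kind[nref == 1L & nalt == 1L] <- "SNP"
  kind[nalt > nref & len <= max_indel] <- "INSERTION"
  kind[nref > nalt & len <= max_indel] <- "DELETION"
  records$kind <- kind
  records$len <- ifelse(kind == "SNP", 0L, len)
  records
}

#' Apply the full retention pipeline to one sample's calls
#'
#' Quality/depth filter, then flank-distance filter, then classification.
#' @param records One sample's call data.frame.
#' @inheritParams filter_quality_depth
#' @inheritParams filter_flank_distance
#' @return List with `kept` (classified) and `removed` (with a `reason`
#'   column: `"quality_depth"` or `"flank"`).
#' @export
filter_sample_calls <- function(records, min_quality = 30, min_depth = 5,
                                min_flank = 5) {
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  qd <- filter_quality_depth(records, min_quality, min_depth)
  fl <- filter_flank_distance(qd$kept, min_flank)
  removed <- rbind(
    if (nrow(qd$removed)) cbind(qd$removed, reason = "quality_depth"),
    if (nrow(fl$removed)) cbind(fl$removed, reason = "flank"))
  if (is.null(removed))
    removed <- cbind(records[0, , drop = FALSE], reason = character(0))
  list(kept = classify_variants(fl$kept), removed = removed)
}
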