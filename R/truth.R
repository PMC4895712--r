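#' Truth set of planted events
#'
#' The machine-readable record of everything the simulator planted: one row
#' per planted genotype call in `variants` (with zygosity, a line-specific
#' flag and, for construction-forced coding variants, the intended effect
#' class), planted per-gene deletion/duplication events in `gene_events`, and
#' planted structural events in `sv_events`.
#'
#' @param variants data.frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `zygosity`, `line_specific`, `effect`.
#' @param gene_events data.frame with columns `sample`, `gene_id`, `event`
#'   (`"deletion"` or `"duplication"`).
#' @param sv_events data.frame with columns `sample`, `type` (`"CTX"`,
#'   `"ITX"`, `"INV"`), `chromA`, `posA`, `chromB`, `posB`.
#' @param genes Optional [gene_models()] used to check that gene events
#'   reference genes of at least 1,000 bp.
#' @param chrom_lengths Optional named vector used to check that breakpoints
#'   lie within chromosome bounds.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(variants, gene_events, sv_events,
                      genes = NULL, chrom_lengths = NULL) {
  ts <- list(variants = as.data.frame(variants),
             gene_events = as.data.frame(gene_events),
             sv_events = as.data.frame(sv_events))
  class(ts) <- "truth_set"

  ls <- ts$variants[isTRUE_vec(ts$variants$line_specific), , drop = FALSE]
  if (nrow(ls)) {
    key <- paste(ls$chrom, ls$pos, ls$ref, ls$alt)
    per_site <- tapply(ls$sample, key, function(s) length(unique(s)))
    if (any(per_site != 1L))
      stop("truth_set: a line-specific variant must occur in exactly one sample")
  }
  if (!is.null(genes) && nrow(ts$gene_events)) {
    len <- gene_lengths(genes)
    if (any(len[ts$gene_events$gene_id] < 1000L))
      stop("truth_set: gene events must reference genes >= 1,000 bp")
  }
  if (!is.null(chrom_lengths) && nrow(ts$sv_events)) {
    sv <- ts$sv_events
    bad <- sv$posA < 1L | sv$posA > chrom_lengths[sv$chromA] |
      sv$posB < 1L | sv$posB > chrom_lengths[sv$chromB]
    if (any(bad))
      stop("truth_set: SV breakpoints must lie within chromosome bounds")
  }
  ts
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$variants), "planted calls (",
      sum(isTRUE_vec(x$variants$line_specific)), "line-specific ),",
      nrow(x$gene_events), "gene events,",
      nrow(x$sv_events), "SV events\n")
  invisible(x)
}
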