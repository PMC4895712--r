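#' Region queries and summary reports
#'
#' Assembles the summary tables of the analysis — the per-sample inter/intra
#' genic SNP table, the type-by-chromosome structural-variant matrix (see
#' [summarize_sv()]), the per-sample line-specific/gene-event table — plus
#' region reports for named intervals (such as a QTL hotspot supplied by the
#' user) and plain-text BED/bedGraph track exports.
#'
#' @name reporting
NULL

#' @rdname reporting
#' @param name Label of the region.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds.
#' @param chrom_lengths Optional named lengths to validate against.
#' @return `region_query()`: a validated list of class `region_query`.
#' @export
region_query <- function(name, chrom, start, end, chrom_lengths = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("region_query: start must not exceed end")
  if (!is.null(chrom_lengths)) {
    if (!chrom %in% names(chrom_lengths))
      stop("region_query: unknown chromosome ", chrom)
    if (start < 1L || end > chrom_lengths[[chrom]])
      stop("region_query: region outside chromosome bounds")
  }
  structure(list(name = name, chrom = chrom, start = start, end = end),
            class = "region_query")
}

#' Per-sample table of inter- and intra-genic SNPs
#'
#' One row per sample counting the sample's non-reference SNP calls by
#' region and coding effect class, with a row total and an appended
#' genome-totals row (cells sum to the row totals by construction).
#' @param panel A `panel_matrix`.
#' @param effects Annotation from [annotate_panel()].
#' @return data.frame, one row per sample plus a `Total` row.
#' @export
table1_report <- function(panel, effects) {
  snp <- panel$sites$kind == "SNP"
  cols <- c(intergenic = "INTERGENIC", intron = "INTRON")
  eff_cols <- c(non_synonymous_coding = "NON_SYNONYMOUS_CODING",
                non_synonymous_start = "NON_SYNONYMOUS_START",
                start_lost = "START_LOST",
                stop_gained = "STOP_GAINED",
                stop_lost = "STOP_LOST",
                synonymous_coding = "SYNONYMOUS_CODING",
                synonymous_stop = "SYNONYMOUS_STOP")
  rows <- lapply(panel$samples, function(s) {
    g <- panel$geno[, s]
    sel <- snp & !is.na(g) & g >= 1L
    r <- vapply(cols, function(rg) sum(sel & effects$region == rg),
                integer(1))
    e <- vapply(eff_cols, function(ef) sum(sel & effects$effect == ef),
                integer(1))
    others <- sum(sel & effects$region == "OTHER")
    data.frame(sample = s, t(r), t(e), others = others,
               total = sum(sel))
  })
  out <- do.call(rbind, rows)
  num <- names(out)[-1]
  total <- c(sample = "Total",
             stats::setNames(as.list(colSums(out[num])), num))
  out <- rbind(out, as.data.frame(total))
  rownames(out) <- NULL
  out
}

#' Report every union site within a named region
#'
#' @param query A [region_query()].
#' @param panel A `panel_matrix`.
#' @param effects Annotation from [annotate_panel()].
#' @return List with `variants` (sites in the region with their annotation),
#'   `effect_breakdown` (counts per effect class) and `affected_genes`
#'   (distinct genes hit by non-synonymous classes in the region).
#' @export
region_report <- function(query, panel, effects) {
  sel <- panel$sites$chrom == query$chrom &
    panel$sites$pos >= query$start & panel$sites$pos <= query$end
  variants <- cbind(panel$sites[sel, , drop = FALSE],
                    effects[sel, , drop = FALSE])
  rownames(variants) <- NULL
  nonsyn <- variants$effect %in% c("NON_SYNONYMOUS_CODING",
                                   "NON_SYNONYMOUS_START")
  list(variants = variants,
       effect_breakdown = table(factor(variants$effect,
                                       levels = effect_levels())),
       affected_genes = sort(unique(variants$gene_id[nonsyn &
                                                     !is.na(variants$gene_id)])))
}

#' Export plain-text analysis tracks
#'
#' Writes, per sample, the line-specific SNP and indel sites as BED and the
#' deleted/duplicated gene spans as BED, plus one genome-wide bedGraph of
#' windowed SNP density — the data tracks of a circular genome plot, ready
#' for rendering elsewhere.
#' @param dir Output directory.
#' @param panel A `panel_matrix`.
#' @param genes A [gene_models()] object.
#' @param windows Window table from [window_counts()].
#' @param events Gene event table (`sample`, `gene_id`, `event`).
#' @return Invisibly, the vector of files written.
#' @export
export_tracks <- function(dir, panel, genes, windows, events) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  write_bed <- function(df, path) {
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
    files <<- c(files, path)
  }
  ls <- line_specific_variants(panel)
  for (s in panel$samples) {
    for (what in c("snps", "indels")) {
      st <- ls[[s]][[what]]
      z <- to_zero_based(st$pos, st$pos)
      nm <- if (nrow(st)) paste0(st$ref, ">", st$alt) else character(0)
      write_bed(data.frame(chrom = st$chrom, start0 = z$start0,
                           end0 = z$end0, name = nm),
                file.path(dir, sprintf("%s.line_specific_%s.bed", s, what)))
    }
    for (ev in c("deletion", "duplication")) {
      gid <- events$gene_id[events$sample == s & events$event == ev]
      g <- genes$genes[match(gid, genes$genes$gene_id), , drop = FALSE]
      z <- to_zero_based(g$start, g$end)
      write_bed(data.frame(chrom = g$chrom, start0 = z$start0,
                           end0 = z$end0, name = gid),
                file.path(dir, sprintf("%s.gene_%ss.bed", s, ev)))
    }
  }
  dens <- data.frame(chrom = windows$chrom, start0 = windows$window_start,
                     end0 = windows$window_end,
                     density = windows$n_snps /
                       ((windows$window_end - windows$window_start) / 1000))
  data.table::fwrite(dens, file.path(dir, "snp_density.bedGraph"),
                     sep = "\t", col.names = FALSE)
  files <- c(files, file.path(dir, "snp_density.bedGraph"))
  invisible(files)
}
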