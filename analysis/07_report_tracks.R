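# Stage 7: region report, plain-text plot tracks, and planted-truth
# recovery. The region query stands in for a user-supplied interval of
# interest (a QTL hotspot, say); here the first half of Ca1.

source("analysis/00_config.R")

panel <- load_study_panel()
kept <- lapply(lapply(panel$calls, filter_sample_calls), `[[`, "kept")
pm <- build_panel(kept, depth = panel$depth)
chrom_lengths <- stats::setNames(Biostrings::width(panel$reference),
                                 names(panel$reference))
effects <- annotate_panel(pm, panel$genes, panel$reference)
windows <- window_counts(pm, chrom_lengths)

query <- region_query("hotspot-demo", "Ca1", 1L, 500000L, chrom_lengths)
rep <- region_report(query, pm, effects)
data.table::fwrite(rep$variants,
                   file.path(results_dir, "region_hotspot_demo.tsv"),
                   sep = "\t")

gene_calls <- lapply(setdiff(names(panel$depth), "control"), function(s)
  call_gene_events(panel$depth[[s]], panel$genes, s))
events <- do.call(rbind, lapply(gene_calls, panelvar:::gene_event_table))
export_tracks(file.path(results_dir, "tracks"), pm, panel$genes, windows,
              events)

ls <- evaluate_line_specific(pm, panel$truth)
ge <- evaluate_gene_events(events, panel$truth)
recovery <- data.frame(
  metric = c("line_specific_precision", "line_specific_recall",
             "gene_deletion_recall", "gene_duplication_recall"),
  value = c(ls$precision, ls$recall, ge$deletion$recall,
            ge$duplication$recall))
data.table::fwrite(recovery, file.path(results_dir, "truth_recovery.tsv"),
                   sep = "\t")

message("region '", query$name, "': ", nrow(rep$variants), " variants, ",
        length(rep$affected_genes), " genes with non-synonymous changes")
message("planted-truth recovery:")
print(recovery)
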