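# Stage 5: depth-based gene presence/absence and duplication calling for
# genes >= 1 kb, with reference-control false-positive exclusion, and the
# panel-level non-redundant / line-specific gene event sets.

source("analysis/00_config.R")

panel <- load_study_panel()
samples <- setdiff(names(panel$depth), "control")

gene_calls <- lapply(c(samples, "control"), function(s)
  call_gene_events(panel$depth[[s]], panel$genes, s))
names(gene_calls) <- c(samples, "control")

events <- do.call(rbind, lapply(samples, function(s)
  panelvar:::gene_event_table(gene_calls[[s]])))
events <- exclude_control(events,
                          panelvar:::gene_event_table(gene_calls$control))
sets <- gene_event_sets(events)

data.table::fwrite(events, file.path(results_dir, "gene_events.tsv"),
                   sep = "\t")
data.table::fwrite(sets$per_gene_sample_counts,
                   file.path(results_dir, "gene_event_counts.tsv"),
                   sep = "\t")

per_sample <- do.call(rbind, lapply(samples, function(s) data.frame(
  sample = s,
  genes_deleted = sum(events$sample == s & events$event == "deletion"),
  genes_duplicated = sum(events$sample == s & events$event == "duplication"))))
data.table::fwrite(per_sample,
                   file.path(results_dir, "gene_events_per_sample.tsv"),
                   sep = "\t")

message("non-redundant duplicated genes: ",
        length(sets$non_redundant_duplicated))
message("non-redundant absent genes:     ",
        length(sets$non_redundant_absent))
message("line-specific gene events:      ", nrow(sets$line_specific))
print(per_sample)
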