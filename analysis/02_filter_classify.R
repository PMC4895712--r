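# Stage 2: apply the retention rules to each genotype's calls and classify
# the survivors. A call is kept when QUAL > 30 and depth >= 5 and no other
# call of the same genotype sits within 5 bp; retained records are classed
# SNP, insertion or deletion (1-58 bp).

source("analysis/00_config.R")

panel <- load_study_panel()
filtered <- lapply(panel$calls, filter_sample_calls)

summary <- do.call(rbind, lapply(names(filtered), function(s) {
  k <- filtered[[s]]$kept
  data.frame(sample = s, input = nrow(panel$calls[[s]]), kept = nrow(k),
             removed = nrow(filtered[[s]]$removed),
             snps = sum(k$kind == "SNP"),
             insertions = sum(k$kind == "INSERTION"),
             deletions = sum(k$kind == "DELETION"))
}))
data.table::fwrite(summary, file.path(results_dir, "filter_summary.tsv"),
                   sep = "\t")
for (s in names(filtered))
  data.table::fwrite(filtered[[s]]$kept,
                     file.path(results_dir, paste0("kept_", s, ".tsv")),
                     sep = "\t")

message("retention summary written to results/filter_summary.tsv")
print(summary)
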