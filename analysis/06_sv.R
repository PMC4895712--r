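# Stage 6: structural-variant typing from discordant read pairs. Pairs with
# mapping quality >= 30 are clustered, typed (CTX/ITX/INV), scored
# min(99, 20 x support), filtered at score 99, and purged of loci supported
# in the reference control; breakpoints are refined from the innermost
# supporting mate edges.

source("analysis/00_config.R")

panel <- load_study_panel()
cfg <- study_config
samples <- setdiff(names(panel$pairs), "control")

control_svs <- call_svs(panel$pairs$control, cfg$insert_size_mean,
                        cfg$insert_size_sd)
calls <- do.call(rbind, lapply(samples, function(s)
  filter_and_exclude(call_svs(panel$pairs[[s]], cfg$insert_size_mean,
                              cfg$insert_size_sd),
                     control_svs, min_score = 99,
                     max_gap = cfg$insert_size_mean +
                       3 * cfg$insert_size_sd)))

sm <- summarize_sv(calls, names(panel$reference))
data.table::fwrite(calls, file.path(results_dir, "sv_calls.tsv"),
                   sep = "\t")
data.table::fwrite(data.frame(type = rownames(sm$matrix), sm$matrix),
                   file.path(results_dir, "sv_type_by_chromosome.tsv"),
                   sep = "\t")
data.table::fwrite(sm$size_ranges,
                   file.path(results_dir, "sv_size_ranges.tsv"), sep = "\t")

message("high-confidence SV calls: ", nrow(calls))
print(sm$matrix)
print(sm$size_ranges)
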