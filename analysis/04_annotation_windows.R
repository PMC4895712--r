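# Stage 4: distribution and annotation statistics. Counts per 100 kb window,
# per-pseudomolecule SNP density / polymorphism rate / exonic variant
# density, the indel length spectrum, and the per-genotype table of inter-
# and intra-genic SNP effects.

source("analysis/00_config.R")

panel <- load_study_panel()
kept <- lapply(lapply(panel$calls, filter_sample_calls), `[[`, "kept")
pm <- build_panel(kept, depth = panel$depth)
chrom_lengths <- stats::setNames(Biostrings::width(panel$reference),
                                 names(panel$reference))

effects <- annotate_panel(pm, panel$genes, panel$reference)
windows <- window_counts(pm, chrom_lengths)
dens <- chromosome_density(pm, chrom_lengths, effects)
spectrum <- indel_spectrum(pm)
t1 <- table1_report(pm, effects)

data.table::fwrite(windows, file.path(results_dir, "window_counts.tsv"),
                   sep = "\t")
data.table::fwrite(dens, file.path(results_dir, "chromosome_density.tsv"),
                   sep = "\t")
data.table::fwrite(spectrum, file.path(results_dir, "indel_spectrum.tsv"),
                   sep = "\t")
data.table::fwrite(t1, file.path(results_dir, "snp_effect_table.tsv"),
                   sep = "\t")

sm <- summarize_effects(pm, effects)
message("per-pseudomolecule SNP density (per kb): ",
        paste(sprintf("%s=%.2f", dens$chrom, dens$snp_density),
              collapse = ", "))
message("genome effect totals: mis-sense ", sm$genome[["mis_sense"]],
        ", non-sense ", sm$genome[["non_sense"]],
        ", silent ", sm$genome[["silent"]])
message("most deletions have length ",
        spectrum$length[which.max(spectrum$n_deletions)], " bp")
print(dens)
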