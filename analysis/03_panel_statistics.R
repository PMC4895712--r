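# Stage 3: merge the filtered calls into the variants x genotypes panel and
# compute the panel statistics: zygosity classes and heterozygosity rate,
# insertion/deletion ratio, pairwise SNP counts, and line-specific variants
# (alternate allele in exactly one genotype, confident reference in all
# others).

source("analysis/00_config.R")

panel <- load_study_panel()
kept <- lapply(lapply(panel$calls, filter_sample_calls), `[[`, "kept")
pm <- build_panel(kept, depth = panel$depth)

ss <- sample_summary(pm)
data.table::fwrite(ss, file.path(results_dir, "sample_summary.tsv"),
                   sep = "\t")
pw <- pairwise_snp_matrix(pm)
data.table::fwrite(data.frame(sample = rownames(pw), pw),
                   file.path(results_dir, "pairwise_snps.tsv"), sep = "\t")

ls <- line_specific_variants(pm)
ls_tab <- do.call(rbind, lapply(names(ls), function(s) {
  st <- rbind(ls[[s]]$snps, ls[[s]]$indels)
  if (!nrow(st)) return(NULL)
  cbind(sample = s, st)
}))
data.table::fwrite(ls_tab, file.path(results_dir, "line_specific.tsv"),
                   sep = "\t")

message("panel of ", nrow(pm$sites), " union sites x ",
        length(pm$samples), " genotypes")
message("mean heterozygosity rate: ",
        round(mean(ss$heterozygosity_rate), 3))
message("line-specific variants per genotype: ",
        paste(ss$ls_snps + ss$ls_indels, collapse = ", "))
print(ss)
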