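# Stage 1: simulate the study panel and write it to disk.
#
# Five re-sequenced genotypes plus a reference control on a 2 x 1 Mb
# two-pseudomolecule genome with 20 genes; roughly 2,000 SNP and 200 indel
# union sites, 25 line-specific variants, 3 gene deletions, 3 gene
# duplications and 3 structural events per type (CTX/ITX/INV) per genotype.

source("analysis/00_config.R")

panel <- simulate_panel(study_config)
write_panel(panel, panel_dir)

tv <- panel$truth$variants
message("simulated panel written to ", panel_dir)
message("  genotypes:            ", length(panel$calls))
message("  genes:                 ", nrow(panel$genes$genes))
message("  planted calls:         ", nrow(tv),
        " (", sum(tv$line_specific), " line-specific)")
message("  planted gene events:   ", nrow(panel$truth$gene_events))
message("  planted SV events:     ", nrow(panel$truth$sv_events))
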