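# Shared settings of the synthetic-panel study. Every numbered script
# sources this file; the panel itself is written once by 01_simulate.R and
# re-read from disk by the later stages.

library(panelvar)

study_seed <- 42L
study_config <- sim_config(seed = study_seed)

panel_dir <- "results/panel"
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

# Reassemble the in-memory panel from the files written by 01_simulate.R.
load_study_panel <- function() {
  p <- read_panel(panel_dir)
  p$config <- study_config
  p
}
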