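#' Simulate a complete synthetic resequencing panel
#'
#' Runs the four generator stages in a fixed order — reference genome and gene
#' models, per-sample variant calls with the panel truth set, per-sample depth
#' profiles, and per-sample discordant read pairs — under a single RNG stream
#' seeded from `config$seed`, so the same configuration and seed reproduce
#' every object and file byte for byte.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_panel` with elements `reference`, `genes`,
#'   `calls`, `depth`, `pairs`, `truth` and `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  ref <- generate_reference(config)
  pv <- simulate_panel_variants(ref$reference, ref$genes, config)
  depth <- simulate_depth_profiles(ref$reference, ref$genes, pv$truth, config)
  pairs <- simulate_discordant_pairs(ref$reference, pv$truth, config)
  out <- list(reference = ref$reference, genes = ref$genes,
              calls = pv$calls, depth = depth, pairs = pairs,
              truth = pv$truth, config = config)
  class(out) <- "sim_panel"
  out
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:", length(x$reference), "chromosomes,",
      nrow(x$genes$genes), "genes,", length(x$calls), "samples\n")
  print(x$truth)
  invisible(x)
}
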