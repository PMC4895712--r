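#' Run the full panel characterization pipeline
#'
#' Convenience driver over the individual stages: per-sample retention
#' filters and classification, panel merging with the depth-aware
#' absence-of-call policy, effect annotation, windowed densities, per-gene
#' CNV/PAV calling with control exclusion, and discordant-pair SV calling
#' with the score-99 filter and control exclusion.
#'
#' @param panel A `sim_panel` from [simulate_panel()] or an equivalent list
#'   with `reference`, `genes`, `calls`, `depth`, `pairs` and `config`.
#' @param window Window width for density tracks.
#' @return List with `filtered` (per-sample kept/removed), `panel_matrix`,
#'   `effects`, `windows`, `densities`, `gene_calls`, `gene_events`
#'   (control-excluded), `event_sets`, `sv_calls` (control-excluded,
#'   score-filtered) and `sv_summary`.
#' @export
run_panel_analysis <- function(panel, window = 100000) {
  cfg <- panel$config
  chrom_lengths <- stats::setNames(Biostrings::width(panel$reference),
                                   names(panel$reference))

  filtered <- lapply(panel$calls, filter_sample_calls)
  kept <- lapply(filtered, `[[`, "kept")
  pm <- build_panel(kept, depth = panel$depth)

  effects <- annotate_panel(pm, panel$genes, panel$reference)
  windows <- window_counts(pm, chrom_lengths, window)
  densities <- chromosome_density(pm, chrom_lengths, effects)

  samples <- names(panel$calls)
  ctrl <- control_sample_name()
  gene_calls <- lapply(c(samples, ctrl), function(s)
    call_gene_events(panel$depth[[s]], panel$genes, s))
  names(gene_calls) <- c(samples, ctrl)
  events <- do.call(rbind, lapply(samples, function(s)
    gene_event_table(gene_calls[[s]])))
  control_events <- gene_event_table(gene_calls[[ctrl]])
  events <- exclude_control(events, control_events)
  event_sets <- gene_event_sets(events)

  max_gap <- cfg$insert_size_mean + 3 * cfg$insert_size_sd
  control_svs <- call_svs(panel$pairs[[ctrl]], cfg$insert_size_mean,
                          cfg$insert_size_sd)
  sv_calls <- do.call(rbind, lapply(samples, function(s)
    filter_and_exclude(call_svs(panel$pairs[[s]], cfg$insert_size_mean,
                                cfg$insert_size_sd),
                       control_svs, min_score = 99, max_gap = max_gap)))
  sv_summary <- summarize_sv(sv_calls, names(chrom_lengths))

  list(filtered = filtered, panel_matrix = pm, effects = effects,
       windows = windows, densities = densities, gene_calls = gene_calls,
       gene_events = events, event_sets = event_sets,
       sv_calls = sv_calls, sv_summary = sv_summary)
}
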