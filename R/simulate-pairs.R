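#' Simulate discordant read-pair evidence for planted structural events
#'
#' For every planted structural event of the owning sample, emits
#' `sv_support` discordant pairs whose mate spans flank the two breakpoints
#' with jitter of at most one insert-size standard deviation:
#'
#' * CTX: mate 1 ends just before `posA` on `chromA` (`+`), mate 2 starts just
#'   after `posB` on `chromB` (`-`).
#' * INV: both mates on one chromosome with identical orientation (`+/+` or
#'   `-/-`, chosen per event), flanking the inverted interval.
#' * ITX: opposite-orientation mates on one chromosome whose separation far
#'   exceeds the concordant insert-size model.
#'
#' The control sample emits an empty table. Mate spans are 0-based half-open,
#' `read_length` wide; mapping quality is 60 for supporting reads.
#'
#' @inheritParams simulate_depth_profiles
#' @param truth [truth_set()] with the planted `sv_events`.
#' @return Named list (samples plus `"control"`) of BEDPE-like data.frames
#'   with columns `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`,
#'   `name`, `mapq`, `strand1`, `strand2`, `sample`.
#' @export
simulate_discordant_pairs <- function(reference, truth, config) {
  validate_sim_config(config)
  sv <- truth$sv_events
  if (nrow(sv)) {
    same <- sv$chromA == sv$chromB
    if (any(same & abs(sv$posB - sv$posA) < config$read_length))
      stop("simulate_discordant_pairs: breakpoints closer than read_length")
  }
  samples <- c(panel_sample_names(config), control_sample_name())
  rl <- config$read_length
  sd_j <- max(1L, as.integer(config$insert_size_sd))

  empty <- data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      name = character(0), mapq = integer(0),
                      strand1 = character(0), strand2 = character(0),
                      sample = character(0))
  out <- lapply(samples, function(s) empty)
  names(out) <- samples

  for (i in seq_len(nrow(sv))) {
    e <- sv[i, ]
    n <- config$sv_support
    dA <- sample(0:sd_j, n, replace = TRUE)
    dB <- sample(0:sd_j, n, replace = TRUE)
    strands <- switch(e$type,
                      CTX = c("+", "-"),
                      ITX = c("+", "-"),
                      INV = if (stats::runif(1) < 0.5) c("+", "+")
                            else c("-", "-"))
    # a '+' mate points at its breakpoint and ends just before it; a '-'
    # mate points away and starts just after it
    if (strands[1] == "+") {
      end1 <- (e$posA - 1L) - dA        # 0-based exclusive inner edge
      start1 <- end1 - rl
    } else {
      start1 <- (e$posA - 1L) + dA      # 0-based inner edge after breakpoint
      end1 <- start1 + rl
    }
    if (strands[2] == "-") {
      start2 <- (e$posB - 1L) + dB
      end2 <- start2 + rl
    } else {
      end2 <- (e$posB - 1L) - dB
      start2 <- end2 - rl
    }
    pr <- data.frame(
      chrom1 = e$chromA, start1 = as.integer(start1), end1 = as.integer(end1),
      chrom2 = e$chromB, start2 = as.integer(start2), end2 = as.integer(end2),
      name = sprintf("%s_%s_%d_rp%d", e$sample, e$type, i, seq_len(n)),
      mapq = 60L, strand1 = strands[1], strand2 = strands[2],
      sample = e$sample)
    out[[e$sample]] <- rbind(out[[e$sample]], pr)
  }
  for (s in samples) {
    d <- out[[s]]
    d <- d[order(d$chrom1, d$start1, d$chrom2, d$start2), , drop = FALSE]
    rownames(d) <- NULL
    out[[s]] <- d
  }
  out
}
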