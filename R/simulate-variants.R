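#' Simulate per-sample variant calls and the panel truth set
#'
#' Plants SNP and indel sites on the reference at the configured panel-level
#' rates (Poisson site counts per chromosome, uniform placement with a minimum
#' inter-site gap so that planted sites never collide under the 5 bp flank
#' rule), assigns each shared site to at least two carrier genotypes, plants
#' `n_line_specific` single-carrier sites per genotype, forces the configured
#' number of coding variants into known effect classes (each verified against
#' the genetic code at generation time), and draws zygosity (heterozygous with
#' probability `het_fraction`), QUAL and per-sample depth for every call.
#'
#' Also plans the per-gene deletion/duplication events and the structural
#' events (CTX/ITX/INV breakpoints) that the depth and discordant-pair
#' simulators realize. Genes scheduled for deletion in any genotype receive no
#' variants: with the gene absent the other genotypes could not be confirmed
#' homozygous-reference there, so such sites would be unrecoverable by
#' construction rather than by method error.
#'
#' @param reference Named [Biostrings::DNAStringSet] from
#'   [generate_reference()].
#' @param genes [gene_models()] object.
#' @param config [sim_config()] object.
#' @return List with `calls` (named list of per-sample call data.frames with
#'   columns `chrom`, `pos`, `ref`, `alt`, `qual`, `dp`, `gt`, `sample`) and
#'   `truth` (a [truth_set()]).
#' @export
simulate_panel_variants <- function(reference, genes, config) {
  validate_sim_config(config)
  samples <- panel_sample_names(config)
  chrom_lengths <- stats::setNames(Biostrings::width(reference),
                                   names(reference))

  pools <- plan_event_pools(genes, config)
  gene_events <- plan_gene_events(pools, config, samples)
  sv_events <- plan_sv_events(chrom_lengths, config, samples)

  gap <- config$indel_length_max + 7L
  forced <- forced_effect_variants(reference, genes, config,
                                   exclude_genes = pools$del_pool, gap = gap)

  sites <- random_sites(reference, genes, config,
                        exclude_genes = pools$del_pool,
                        forced_pos = forced[, c("chrom", "pos")], gap = gap)

  # roles: line-specific assignment among the random sites
  n_ls_total <- config$n_line_specific * config$n_samples
  if (n_ls_total > nrow(sites))
    stop("simulate_panel_variants: not enough sites to plant ",
         n_ls_total, " line-specific variants; raise the rates")
  sites$ls_sample <- rep(NA_character_, nrow(sites))
  if (n_ls_total > 0L) {
    ls_idx <- sample.int(nrow(sites), n_ls_total)
    sites$ls_sample[ls_idx] <- rep(samples, each = config$n_line_specific)
  }
  sites$effect <- rep(NA_character_, nrow(sites))

  if (nrow(forced)) {
    forced$ls_sample <- NA_character_
    all_sites <- rbind(sites[, names(forced)], forced)
  } else {
    all_sites <- sites
  }
  ord <- order(all_sites$chrom, all_sites$pos)
  all_sites <- all_sites[ord, , drop = FALSE]

  calls_truth <- assign_carriers(all_sites, samples, config)

  truth <- truth_set(calls_truth$truth_variants, gene_events, sv_events,
                     genes = genes, chrom_lengths = chrom_lengths)
  list(calls = calls_truth$calls, truth = truth)
}

panel_sample_names <- function(config) sprintf("S%02d", seq_len(config$n_samples))

#' @keywords internal
control_sample_name <- function() "control"

# --- event planning -----------------------------------------------------

# Disjoint pools of candidate genes for deletion and duplication events.
plan_event_pools <- function(genes, config) {
  len <- gene_lengths(genes)
  eligible <- names(len)[len >= 1000L]
  need_del <- config$n_gene_deletions
  need_dup <- config$n_gene_duplications
  size_del <- if (need_del > 0L) need_del + 2L else 0L
  size_dup <- if (need_dup > 0L) need_dup + 2L else 0L
  if (size_del + size_dup > length(eligible)) {
    size_del <- max(need_del, min(size_del, length(eligible) - need_dup))
    size_dup <- length(eligible) - size_del
  }
  if (need_del > size_del || need_dup > size_dup)
    stop("simulate_panel_variants: too few genes >= 1,000 bp for the ",
         "requested gene events")
  del_pool <- if (size_del) sample(eligible, size_del) else character(0)
  dup_pool <- if (size_dup) sample(setdiff(eligible, del_pool), size_dup)
              else character(0)
  list(del_pool = del_pool, dup_pool = dup_pool)
}

plan_gene_events <- function(pools, config, samples) {
  ev <- list()
  for (s in samples) {
    if (config$n_gene_deletions > 0L)
      ev[[length(ev) + 1L]] <- data.frame(
        sample = s, gene_id = sample(pools$del_pool, config$n_gene_deletions),
        event = "deletion")
    if (config$n_gene_duplications > 0L)
      ev[[length(ev) + 1L]] <- data.frame(
        sample = s, gene_id = sample(pools$dup_pool, config$n_gene_duplications),
        event = "duplication")
  }
  if (!length(ev))
    return(data.frame(sample = character(0), gene_id = character(0),
                      event = character(0)))
  do.call(rbind, ev)
}

plan_sv_events <- function(chrom_lengths, config, samples) {
  empty <- data.frame(sample = character(0), type = character(0),
                      chromA = character(0), posA = integer(0),
                      chromB = character(0), posB = integer(0))
  if (config$n_sv_per_type == 0L) return(empty)
  chroms <- names(chrom_lengths)
  margin <- as.integer(10 * config$insert_size_mean)
  minsep <- as.integer(5 * (config$insert_size_mean + 3 * config$insert_size_sd))
  if (config$n_sv_per_type > 0L && length(chroms) < 2L)
    stop("plan_sv_events: CTX events require at least two chromosomes")

  used <- lapply(chroms, function(x) integer(0))
  names(used) <- chroms
  pick_pos <- function(chrom, lo, hi) {
    for (i in 1:200) {
      p <- sample(lo:hi, 1)
      if (!length(used[[chrom]]) || min(abs(used[[chrom]] - p)) >= minsep) {
        used[[chrom]] <<- c(used[[chrom]], p)
        return(p)
      }
    }
    stop("plan_sv_events: could not place breakpoints ", minsep, " bp apart")
  }

  out <- list()
  for (s in samples) {
    for (type in c("CTX", "ITX", "INV")) {
      for (i in seq_len(config$n_sv_per_type)) {
        if (type == "CTX") {
          cc <- sample(chroms, 2)
          pA <- pick_pos(cc[1], margin, chrom_lengths[[cc[1]]] - margin)
          pB <- pick_pos(cc[2], margin, chrom_lengths[[cc[2]]] - margin)
          out[[length(out) + 1L]] <- data.frame(
            sample = s, type = type, chromA = cc[1], posA = pA,
            chromB = cc[2], posB = pB)
        } else {
          placed <- FALSE
          for (try_i in 1:200) {
            chrom <- sample(chroms, 1)
            size <- if (type == "INV") sample(5000:50000, 1)
                    else sample(10000:200000, 1)
            pA <- sample(margin:(chrom_lengths[[chrom]] - margin - size), 1)
            pB <- pA + size
            u <- used[[chrom]]
            if (length(u) && (min(abs(u - pA)) < minsep ||
                              min(abs(u - pB)) < minsep)) next
            used[[chrom]] <- c(u, pA, pB)
            out[[length(out) + 1L]] <- data.frame(
              sample = s, type = type, chromA = chrom, posA = pA,
              chromB = chrom, posB = pB)
            placed <- TRUE
            break
          }
          if (!placed)
            stop("plan_sv_events: could not place breakpoints ", minsep,
                 " bp apart")
        }
      }
    }
  }
  do.call(rbind, out)
}

# --- site placement -----------------------------------------------------

# n positions in [lo, hi], uniform, pairwise gaps > gap. Exact count.
spaced_positions <- function(n, lo, hi, gap) {
  if (n == 0L) return(integer(0))
  width <- hi - lo + 1L
  avail <- width - (n - 1L) * gap
  if (avail < n)
    stop("spaced_positions: rates too high for the required flank spacing")
  y <- sort(sample.int(avail, n))
  as.integer(lo - 1L + y + (seq_len(n) - 1L) * gap)
}

random_sites <- function(reference, genes, config, exclude_genes,
                         forced_pos, gap) {
  chrom_names <- names(reference)
  out <- list()
  for (chrom in chrom_names) {
    L <- Biostrings::width(reference)[match(chrom, chrom_names)]
    n_snp <- stats::rpois(1, config$snp_rate * L)
    n_ind <- stats::rpois(1, config$indel_rate * L)
    n <- n_snp + n_ind
    if (n == 0L) next
    pos <- spaced_positions(n, 2L, L - config$indel_length_max - 2L, gap)

    drop <- rep(FALSE, n)
    gdel <- genes$genes[genes$genes$gene_id %in% exclude_genes &
                          genes$genes$chrom == chrom, , drop = FALSE]
    if (nrow(gdel)) {
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(pos, pos),
        IRanges::IRanges(gdel$start - 100L, gdel$end + 100L))
      drop <- drop | hit
    }
    fp <- forced_pos$pos[forced_pos$chrom == chrom]
    if (length(fp)) {
      near <- vapply(pos, function(p) any(abs(fp - p) <= gap), logical(1))
      drop <- drop | near
    }
    pos <- pos[!drop]
    m <- length(pos)
    if (m == 0L) next
    kind <- sample(c(rep("SNP", n_snp), rep("IND", n_ind)))[seq_len(m)]

    ref_anchor <- chrom_bases(reference, chrom, pos)
    ref <- ref_anchor
    alt <- character(m)
    klass <- character(m)
    len <- integer(m)
    for (i in seq_len(m)) {
      if (kind[i] == "SNP") {
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref_anchor[i]), 1)
        klass[i] <- "SNP"
        len[i] <- 0L
      } else {
        l <- sample.int(config$indel_length_max, 1)
        if (stats::runif(1) < 0.5) {
          ref[i] <- chrom_substr(reference, chrom, pos[i], pos[i] + l)
          alt[i] <- ref_anchor[i]
          klass[i] <- "DELETION"
        } else {
          alt[i] <- paste0(ref_anchor[i],
                           paste(random_bases(l), collapse = ""))
          klass[i] <- "INSERTION"
        }
        len[i] <- l
      }
    }
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                               kind = klass, len = len)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), len = integer(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# --- carrier assignment -------------------------------------------------

assign_carriers <- function(all_sites, samples, config) {
  n_samples <- length(samples)
  n_sites <- nrow(all_sites)
  carrier_list <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    if (!is.na(all_sites$ls_sample[i])) {
      carrier_list[[i]] <- all_sites$ls_sample[i]
    } else if (n_samples >= 2L) {
      k <- 2L + stats::rbinom(1, max(0L, n_samples - 2L), 0.5)
      carrier_list[[i]] <- sample(samples, k)
    } else {
      carrier_list[[i]] <- samples
    }
  }
  if (n_sites == 0L) {
    tv <- data.frame(sample = character(0), chrom = character(0),
                     pos = integer(0), ref = character(0),
                     alt = character(0), zygosity = character(0),
                     line_specific = logical(0), effect = character(0))
  } else {
    reps <- lengths(carrier_list)
    idx <- rep(seq_len(n_sites), reps)
    tv <- data.frame(
      sample = unlist(carrier_list, use.names = FALSE),
      chrom = all_sites$chrom[idx], pos = all_sites$pos[idx],
      ref = all_sites$ref[idx], alt = all_sites$alt[idx],
      zygosity = ifelse(stats::runif(length(idx)) < config$het_fraction,
                        "het", "hom_alt"),
      line_specific = !is.na(all_sites$ls_sample)[idx],
      effect = all_sites$effect[idx])
  }
  tv$qual <- round(stats::runif(nrow(tv), 35, 60), 1)
  tv$dp <- pmax(5L, stats::rpois(nrow(tv), config$base_depth))

  calls <- lapply(samples, function(s) {
    d <- tv[tv$sample == s, c("chrom", "pos", "ref", "alt", "qual", "dp",
                              "zygosity", "sample"), drop = FALSE]
    names(d)[names(d) == "zygosity"] <- "gt"
    d <- d[order(d$chrom, d$pos), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(calls) <- samples
  truth_variants <- tv[, c("sample", "chrom", "pos", "ref", "alt",
                           "zygosity", "line_specific", "effect")]
  rownames(truth_variants) <- NULL
  list(calls = calls, truth_variants = truth_variants)
}

# --- forced effect variants --------------------------------------------

# Plant coding variants whose effect class is fixed by construction; every
# planted edit is re-classified from the genetic code before acceptance.
forced_effect_variants <- function(reference, genes, config, exclude_genes,
                                   gap) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), len = integer(0),
                      effect = character(0))
  fe <- config$forced_effects
  fe <- fe[fe > 0L]
  if (!length(fe)) return(empty)
  pool <- setdiff(genes$genes$gene_id, exclude_genes)
  if (!length(pool))
    stop("forced_effect_variants: no genes available outside deletion pool")

  placed <- empty
  occupied <- data.frame(chrom = character(0), pos = integer(0))
  too_close <- function(chrom, pos) {
    p <- occupied$pos[occupied$chrom == chrom]
    length(p) && min(abs(p - pos)) <= gap
  }
  for (cat in names(fe)) {
    for (rep_i in seq_len(fe[[cat]])) {
      ok <- FALSE
      for (attempt in 1:200) {
        gid <- sample(pool, 1)
        cand <- plan_forced_edit(reference, genes, gid, cat)
        if (is.null(cand)) next
        if (too_close(cand$chrom, cand$pos)) next
        # generation-time oracle: the planted edit must classify as intended
        chk <- classify_planted_edit(reference, genes, gid, cand)
        if (!identical(chk, cat))
          stop("forced_effect_variants: planted ", cat,
               " classified as ", chk)
        occupied <- rbind(occupied,
                          data.frame(chrom = cand$chrom, pos = cand$pos))
        placed <- rbind(placed, data.frame(
          chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
          kind = cand$kind, len = cand$len, effect = cat))
        ok <- TRUE
        break
      }
      if (!ok)
        stop("forced_effect_variants: could not place a ", cat, " variant")
    }
  }
  placed
}

# Propose one edit of the requested class in the given gene, or NULL if this
# gene/codon draw offers none.
plan_forced_edit <- function(reference, genes, gene_id, category) {
  g <- genes$genes[genes$genes$gene_id == gene_id, ]
  strand <- g$strand
  chrom <- g$chrom
  posvec <- cds_genomic_positions(genes, gene_id)
  n_cod <- length(posvec) %/% 3L
  coding <- cds_coding_seq(genes, gene_id, reference)

  if (category %in% c("FRAME_SHIFT", "CODON_INSERTION", "CODON_DELETION")) {
    seg <- genes$cds[genes$cds$gene_id == gene_id, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    si <- sample.int(nrow(seg), 1)
    l <- if (category == "FRAME_SHIFT") 1L else 3L
    lo <- seg$start[si] + 10L
    hi <- seg$end[si] - 10L - l
    if (hi <= lo) return(NULL)
    pos <- sample(lo:hi, 1)
    anchor <- chrom_bases(reference, chrom, pos)
    if (category == "CODON_DELETION") {
      return(list(chrom = chrom, pos = pos,
                  ref = chrom_substr(reference, chrom, pos, pos + l),
                  alt = anchor, kind = "DELETION", len = l))
    }
    return(list(chrom = chrom, pos = pos, ref = anchor,
                alt = paste0(anchor, paste(random_bases(l), collapse = "")),
                kind = "INSERTION", len = l))
  }

  ci <- switch(category,
               START_LOST = 1L,
               NON_SYNONYMOUS_START = 1L,
               STOP_LOST = n_cod,
               sample(2:(n_cod - 1L), 1))
  ref_codon <- substr(coding, (ci - 1L) * 3L + 1L, ci * 3L)
  cands <- list()
  for (cp in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(ref_codon, cp, cp))) {
      alt_codon <- ref_codon
      substr(alt_codon, cp, cp) <- b
      if (classify_codon_change(ref_codon, alt_codon, ci, n_cod) == category)
        cands[[length(cands) + 1L]] <- c(cp = cp, b = b)
    }
  }
  if (!length(cands)) return(NULL)
  pick <- cands[[sample.int(length(cands), 1)]]
  cp <- as.integer(pick[["cp"]])
  b <- pick[["b"]]
  gpos <- posvec[(ci - 1L) * 3L + cp]
  ref_g <- chrom_bases(reference, chrom, gpos)
  alt_g <- if (strand == "+") b else comp_base(b)
  list(chrom = chrom, pos = gpos, ref = ref_g, alt = alt_g,
       kind = "SNP", len = 0L)
}

# Re-derive the effect class of a planted edit directly from the gene model
# and genetic code (generation-time check).
classify_planted_edit <- function(reference, genes, gene_id, cand) {
  if (cand$kind != "SNP") {
    l <- cand$len
    return(if (l %% 3L != 0L) "FRAME_SHIFT"
           else if (cand$kind == "INSERTION") "CODON_INSERTION"
           else "CODON_DELETION")
  }
  posvec <- cds_genomic_positions(genes, gene_id)
  idx <- match(cand$pos, posvec)
  strand <- genes$genes$strand[match(gene_id, genes$genes$gene_id)]
  coding <- cds_coding_seq(genes, gene_id, reference)
  ci <- (idx - 1L) %/% 3L + 1L
  cp <- (idx - 1L) %% 3L + 1L
  n_cod <- length(posvec) %/% 3L
  ref_codon <- substr(coding, (ci - 1L) * 3L + 1L, ci * 3L)
  alt_base <- if (strand == "+") cand$alt else comp_base(cand$alt)
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- alt_base
  classify_codon_change(ref_codon, alt_codon, ci, n_cod)
}
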